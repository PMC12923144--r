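#' Biogeographic partition
#'
#' Province and depth-zone partitions used to derive range masks for species
#' without an expert range map: a pelagic/benthic province raster (integer
#' ids, `NA` on land), depth-zone raster coded by the benthic vocabulary
#' (`coastal_upper_bathyal`, `bathyal`, `abyssal`, `hadal`), and optionally a
#' finer unit raster inside the Arctic province.
#'
#' @param grid An [sdm_grid()].
#' @param provinces Integer matrix of province ids (`NA` off-ocean).
#' @param depth_zones Integer matrix with values 1-4 indexing
#'   `c("coastal_upper_bathyal", "bathyal", "abyssal", "hadal")`.
#' @param arctic_units Optional integer matrix of finer Arctic units.
#' @param arctic_province_id Province id of the Arctic province, if any.
#' @return A `bio_partition` object.
#' @export
bio_partition <- function(grid, provinces, depth_zones,
                          arctic_units = NULL, arctic_province_id = NA) {
  dims <- grid_dim(grid)
  stopifnot(all(dim(provinces) == dims), all(dim(depth_zones) == dims))
  structure(
    list(grid = grid, provinces = provinces, depth_zones = depth_zones,
         arctic_units = arctic_units, arctic_province_id = arctic_province_id),
    class = "bio_partition"
  )
}

depth_zone_levels <- function() {
  c("coastal_upper_bathyal", "bathyal", "abyssal", "hadal")
}

#' Range mask pair (biogeographical + potential)
#'
#' @param grid An [sdm_grid()].
#' @param br,pr Logical matrices: biogeographical and potential range.
#' @param provenance `"erm"` or `"derived"`.
#' @param taxon_id Species identifier.
#' @return A `range_set` with spherical areas attached.
#' @export
range_set <- function(grid, br, pr, provenance, taxon_id = NA_character_) {
  structure(
    list(
      taxon_id = taxon_id, grid = grid, br = br, pr = pr,
      provenance = match.arg(provenance, c("erm", "derived")),
      area_km2 = c(br = mask_area_km2(br, grid), pr = mask_area_km2(pr, grid))
    ),
    class = "range_set"
  )
}

#' @export
print.range_set <- function(x, ...) {
  cat(sprintf(
    "<range_set> %s (%s): BR %d cells (%.0f km2), PR %d cells (%.0f km2)\n",
    x$taxon_id, x$provenance, sum(x$br), x$area_km2["br"],
    sum(x$pr), x$area_km2["pr"]
  ))
  invisible(x)
}

buffer_and_mask <- function(pre, grid, ocean, buffer_deg) {
  k <- as.integer(round(buffer_deg / grid$res))
  basin <- grow_region(pre & ocean, ocean)
  dilate_mask(pre, k) & basin
}

#' Build ranges from an expert range map
#'
#' The biogeographical range (BR) is the expert polygon buffered by 1 degree
#' of longitude and latitude; the potential range (PR) uses a 10 degree
#' buffer. Both are clipped to the ocean basin(s) the original map touches
#' (connected components of the ocean mask) so land is excluded and the
#' buffer cannot jump basins.
#'
#' @param erm Logical matrix: the expert range rasterised on `grid`.
#' @param grid An [sdm_grid()].
#' @param ocean Logical ocean mask on `grid`.
#' @param buffer_br,buffer_pr Buffers in degrees (defaults 1 and 10).
#' @param taxon_id Species identifier.
#' @return A [range_set()] with provenance `"erm"`.
#' @export
build_from_erm <- function(erm, grid, ocean, buffer_br = 1, buffer_pr = 10,
                           taxon_id = NA_character_) {
  if (!any(erm & ocean)) {
    stop("expert range map does not intersect the ocean", call. = FALSE)
  }
  br <- buffer_and_mask(erm, grid, ocean, buffer_br)
  pr <- buffer_and_mask(erm, grid, ocean, buffer_pr)
  range_set(grid, br, pr, "erm", taxon_id)
}

#' Bounding box of surviving occurrences
#'
#' Axis-aligned box spanning the extreme coordinates of non-erroneous
#' records. A single surviving record yields a degenerate box inflated by one
#' grid cell so downstream geometry stays valid.
#'
#' @param records Occurrence tibble; rows flagged `0` are ignored.
#' @param res Grid resolution (degrees) used to inflate degenerate boxes.
#' @return Numeric length-4 box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @export
bounding_box_from_occurrences <- function(records, res = 0.05) {
  records <- as_occurrence_tbl(records)
  valid <- records[is.na(records$flag) | records$flag != 0L, , drop = FALSE]
  if (nrow(valid) == 0) {
    stop("no surviving occurrence records to bound", call. = FALSE)
  }
  box <- c(min(valid$lon), max(valid$lon), min(valid$lat), max(valid$lat))
  if (box[1] == box[2]) box[1:2] <- box[1:2] + c(-res, res)
  if (box[3] == box[4]) box[3:4] <- box[3:4] + c(-res, res)
  box
}

#' Merge bounding boxes by extreme coordinates
#'
#' @param ... Numeric length-4 boxes.
#' @return The enclosing box.
#' @export
merge_boxes <- function(...) {
  boxes <- do.call(rbind, list(...))
  c(min(boxes[, 1]), max(boxes[, 2]), min(boxes[, 3]), max(boxes[, 4]))
}

box_mask <- function(grid, box) {
  outer(
    grid$lat >= box[3] & grid$lat <= box[4],
    grid$lon >= box[1] & grid$lon <= box[2],
    "&"
  )
}

#' Thinning distance rule
#'
#' No spatial thinning up to 1,000 records; 20 km for more than 1,000 up to
#' 5,000; 30 km above 5,000.
#'
#' @param n Number of occurrence records.
#' @return Thinning distance in km (`0` = no thinning).
#' @export
thin_distance_km <- function(n) {
  if (n <= 1000) 0 else if (n <= 5000) 20 else 30
}

#' Spatial thinning of occurrence records
#'
#' Greedy seed-deterministic thinning: records are visited in a seeded random
#' order and kept when at least the thinning distance (great-circle) from
#' every record already kept. The distance follows [thin_distance_km()]
#' unless overridden.
#'
#' @param records Occurrence tibble.
#' @param seed Integer seed (selection is deterministic given the seed).
#' @param distance_km Override the automatic distance rule (km); `0` skips
#'   thinning.
#' @return Thinned tibble in original row order; attribute `thin_km` records
#'   the distance used.
#' @export
spatial_thin <- function(records, seed = 1L, distance_km = NULL) {
  records <- as_occurrence_tbl(records)
  n <- nrow(records)
  d <- distance_km %||% thin_distance_km(n)
  if (d <= 0 || n <= 1) {
    attr(records, "thin_km") <- 0
    return(records)
  }
  ord <- with_seed(seed, sample.int(n))
  keep <- integer(0)
  klon <- numeric(0); klat <- numeric(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        min(haversine_km(records$lon[i], records$lat[i], klon, klat)) >= d) {
      keep <- c(keep, i)
      klon <- c(klon, records$lon[i]); klat <- c(klat, records$lat[i])
    }
  }
  out <- records[sort(keep), , drop = FALSE]
  attr(out, "thin_km") <- d
  out
}

#' Retain units above an occurrence-share threshold
#'
#' The retention rule behind the province / depth-layer / Arctic-unit
#' filters: keep each unit whose share of total occurrences strictly exceeds
#' the threshold (`per_unit`, default), or drop the smallest units until the
#' dropped mass reaches the threshold (`cumulative`).
#'
#' @param counts Named vector of occurrence counts per unit.
#' @param threshold Share threshold (default 0.033).
#' @param mode `"per_unit"` or `"cumulative"`.
#' @param total Total used for shares (defaults to `sum(counts)`).
#' @return Names of the retained units.
#' @export
retain_by_share <- function(counts, threshold = 0.033,
                            mode = c("per_unit", "cumulative"),
                            total = sum(counts)) {
  mode <- match.arg(mode)
  shares <- tibble::tibble(unit = seq_along(counts),
                           count = as.integer(counts),
                           share = counts / total)
  keep <- filter_units(shares, threshold, mode)
  names(counts)[keep] %||% as.character(keep)
}

share_by_unit <- function(unit_values, total) {
  tab <- table(unit_values, useNA = "no")
  tibble::tibble(
    unit = as.integer(names(tab)),
    count = as.integer(tab),
    share = as.integer(tab) / total
  )
}

filter_units <- function(shares, threshold, mode = c("per_unit", "cumulative")) {
  mode <- match.arg(mode)
  if (mode == "per_unit") {
    return(shares$unit[shares$share > threshold])
  }
  # cumulative tail cut: drop smallest units while the dropped mass stays
  # at or below the threshold
  ord <- order(shares$share)
  cum <- cumsum(shares$share[ord])
  drop <- ord[cum <= threshold]
  shares$unit[setdiff(seq_len(nrow(shares)), drop)]
}

#' Derive a range from occurrences and biogeographic partitions
#'
#' For species without an expert map. Pelagic species start from pelagic
#' provinces intersecting the occurrence bounding box (pelagic-neritic
#' species first restricted to the coastal 0-800 m zone) and keep provinces
#' holding more than `province_share` of the records. Benthic/demersal
#' species keep depth layers and provinces each holding more than
#' `province_share` of records, the range being their intersection
#' (reef-associated species restricted to the coastal zone). Within the
#' Arctic province, only finer Arctic units holding more than `arctic_share`
#' of records are retained. The resulting pre-buffer range is then buffered
#' into BR/PR exactly as [build_from_erm()] does.
#'
#' @param records Cleaned, bounding-box-filtered, spatially thinned
#'   occurrence tibble (erroneous rows ignored).
#' @param profile One-row profile from [species_profile()].
#' @param partition A [bio_partition()].
#' @param ocean Logical ocean mask.
#' @param province_share Province/depth-layer retention threshold (strict
#'   `>`), default 0.033.
#' @param arctic_share Arctic-unit retention threshold, default 0.005.
#' @param filter_mode `"per_unit"` (each unit's own share must exceed the
#'   threshold; default) or `"cumulative"` (smallest units dropped until the
#'   dropped mass reaches the threshold).
#' @param buffer_br,buffer_pr Degree buffers as in [build_from_erm()].
#' @return A [range_set()] with provenance `"derived"`.
#' @export
derive_range <- function(records, profile, partition, ocean,
                         province_share = 0.033, arctic_share = 0.005,
                         filter_mode = c("per_unit", "cumulative"),
                         buffer_br = 1, buffer_pr = 10) {
  filter_mode <- match.arg(filter_mode)
  records <- as_occurrence_tbl(records)
  valid <- records[is.na(records$flag) | records$flag != 0L, , drop = FALSE]
  if (nrow(valid) == 0) stop("no valid occurrence records", call. = FALSE)
  grid <- partition$grid
  box <- bounding_box_from_occurrences(valid, res = grid$res)
  bmask <- box_mask(grid, box)

  idx <- cell_of(grid, valid$lon, valid$lat)
  ok <- !is.na(idx$cell)
  rc <- cbind(idx$row[ok], idx$col[ok])
  n_total <- sum(ok)
  if (n_total == 0) stop("no occurrence falls on the grid", call. = FALSE)
  prov_at <- partition$provinces[rc]
  zone_at <- partition$depth_zones[rc]

  coastal <- !is.na(partition$depth_zones) & partition$depth_zones == 1L
  bottom <- profile$bottom_class

  if (bottom == "pelagic") {
    cand <- !is.na(partition$provinces) & bmask
    if (identical(profile$coast_class, "neritic")) cand <- cand & coastal
    cand_prov <- unique(partition$provinces[cand])
    shares <- share_by_unit(prov_at[prov_at %in% cand_prov], n_total)
    keep <- filter_units(shares, province_share, filter_mode)
    if (length(keep) == 0) {
      stop("all provinces fell below the retention threshold; ",
           "consider relaxing province_share", call. = FALSE)
    }
    pre <- cand & matrix(partition$provinces %in% keep, nrow(cand))
  } else {
    zshares <- share_by_unit(zone_at, n_total)
    keep_z <- filter_units(zshares, province_share, filter_mode)
    pshares <- share_by_unit(prov_at, n_total)
    keep_p <- filter_units(pshares, province_share, filter_mode)
    if (length(keep_z) == 0 || length(keep_p) == 0) {
      stop("all depth layers or provinces fell below the retention ",
           "threshold; consider relaxing province_share", call. = FALSE)
    }
    zmask <- matrix(partition$depth_zones %in% keep_z, nrow(bmask))
    pmask <- matrix(partition$provinces %in% keep_p, nrow(bmask))
    pre <- bmask & zmask & pmask
    if (identical(profile$habitat_label, "reef-associated")) {
      pre <- pre & coastal
    }
  }

  # Arctic refinement on the finer unit partition
  if (!is.null(partition$arctic_units) && !is.na(partition$arctic_province_id)) {
    in_arctic <- !is.na(partition$provinces) &
      partition$provinces == partition$arctic_province_id
    if (any(pre & in_arctic)) {
      unit_at <- partition$arctic_units[rc]
      unit_at <- unit_at[!is.na(prov_at) & prov_at == partition$arctic_province_id]
      ushares <- share_by_unit(unit_at[!is.na(unit_at)], n_total)
      keep_u <- filter_units(ushares, arctic_share, "per_unit")
      keep_mask <- matrix(partition$arctic_units %in% keep_u, nrow(pre))
      pre <- pre & (!in_arctic | keep_mask)
    }
  }

  if (!any(pre & ocean)) {
    stop("derived range is empty after filtering; ",
         "consider relaxing province_share", call. = FALSE)
  }
  br <- buffer_and_mask(pre, grid, ocean, buffer_br)
  pr <- buffer_and_mask(pre, grid, ocean, buffer_pr)
  range_set(grid, br, pr, "derived", profile$taxon_id)
}

#' Re-flag occurrences by biogeographical-range membership
#'
#' Unflagged or verified records inside the BR become verified (`flag = 1`);
#' records outside it — including any on land, since the BR excludes land —
#' become erroneous (`flag = 0`). Records already flagged erroneous stay
#' erroneous. Every record ends up flagged one way or the other.
#'
#' @param records Occurrence tibble.
#' @param rset A [range_set()].
#' @return The tibble with `flag` rewritten.
#' @export
reflag_by_range <- function(records, rset) {
  records <- as_occurrence_tbl(records)
  idx <- cell_of(rset$grid, records$lon, records$lat)
  inside <- rep(FALSE, nrow(records))
  ok <- !is.na(idx$cell)
  inside[ok] <- rset$br[cbind(idx$row[ok], idx$col[ok])]
  was_bad <- !is.na(records$flag) & records$flag == 0L
  records$flag <- ifelse(inside & !was_bad, 1L, 0L)
  records
}
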