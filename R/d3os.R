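#' Three-axis ocean habitat classification
#'
#' Species habitats are summarised along three spatial axes: distance to
#' bottom (`pelagic` / `demersal` / `benthic`), distance to coast (`neritic` /
#' `oceanic` / `generalist`), and distance to surface (membership in vertical
#' depth zones). The pelagic vertical vocabulary is `epipelagic` (0-200 m),
#' `mesopelagic` (200-1000 m), `bathypelagic` (>1000 m); the benthic/demersal
#' vocabulary follows the benthic-province depth zones `coastal_upper_bathyal`
#' (0-800 m), `bathyal` (800-3500 m), `abyssal` (3500-6500 m), `hadal`
#' (>6500 m).
#'
#' @name d3os
NULL

pelagic_zones <- function() {
  tibble::tibble(
    zone = c("epipelagic", "mesopelagic", "bathypelagic"),
    lower = c(0, 200, 1000),
    upper = c(200, 1000, Inf)
  )
}

benthic_zones <- function() {
  tibble::tibble(
    zone = c("coastal_upper_bathyal", "bathyal", "abyssal", "hadal"),
    lower = c(0, 800, 3500, 6500),
    upper = c(800, 3500, 6500, Inf)
  )
}

bottom_class_map <- function() {
  c(
    "pelagic" = "pelagic", "pelagic-oceanic" = "pelagic",
    "bathypelagic" = "pelagic", "pelagic-neritic" = "pelagic",
    "demersal" = "demersal", "benthopelagic" = "demersal",
    "bathydemersal" = "demersal",
    "benthic" = "benthic", "reef-associated" = "benthic"
  )
}

#' Classify distance to bottom from a habitat label
#'
#' @param habitat_label Habitat vocabulary string (case-insensitive):
#'   `pelagic`, `pelagic-oceanic`, `bathypelagic`, `pelagic-neritic` map to
#'   `pelagic`; `demersal`, `benthopelagic`, `bathydemersal` to `demersal`;
#'   `benthic`, `reef-associated` to `benthic`.
#' @return One of `"pelagic"`, `"demersal"`, `"benthic"` (vectorised).
#' @export
classify_bottom <- function(habitat_label) {
  key <- tolower(trimws(habitat_label))
  out <- unname(bottom_class_map()[key])
  if (anyNA(out)) {
    bad <- unique(habitat_label[is.na(out)])
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Classify distance to coast from occurrence placement
#'
#' Computes the share of valid occurrence records falling in the coastal
#' (0-800 m) zone. A share of at least `threshold` gives `neritic`, at most
#' `1 - threshold` gives `oceanic`, anything in between `generalist`.
#'
#' @param records Cleaned occurrence tibble; rows flagged `0` are ignored.
#' @param coastal_mask Logical matrix on `grid`: the 0-800 m depth zone.
#' @param grid An [sdm_grid()].
#' @param threshold Coastal-share cut, default 0.9.
#' @return A list with `coast_class` and the observed coastal share `p`.
#' @export
classify_coast <- function(records, coastal_mask, grid, threshold = 0.9) {
  records <- as_occurrence_tbl(records)
  valid <- records[is.na(records$flag) | records$flag != 0L, , drop = FALSE]
  if (nrow(valid) == 0) {
    stop("no valid occurrence records to classify distance to coast",
         call. = FALSE)
  }
  idx <- cell_of(grid, valid$lon, valid$lat)
  on_grid <- !is.na(idx$cell)
  inside <- rep(FALSE, nrow(valid))
  inside[on_grid] <- coastal_mask[cbind(idx$row[on_grid], idx$col[on_grid])]
  p <- mean(inside)
  cls <- if (p >= threshold) "neritic"
  else if (p <= 1 - threshold) "oceanic"
  else "generalist"
  list(coast_class = cls, p = p)
}

zones_overlapping <- function(zones, lo, hi) {
  # closed-interval overlap: touching a zone edge counts
  keep <- zones$lower <= hi & zones$upper >= lo
  zones$zone[keep]
}

#' Classify vertical (distance to surface) zone membership
#'
#' Pelagic species: the trait depth range is buffered by 30 m (floored at 0)
#' and every pelagic zone the buffered interval overlaps is returned.
#' Benthic/demersal species: with a depth range, the overlapped
#' benthic-province depth zones are returned (no buffer); without one, every
#' zone holding more than 10% of the valid records (by bathymetric depth at
#' the record location) is returned.
#'
#' @param bottom_class `"pelagic"`, `"demersal"` or `"benthic"`.
#' @param depth_min,depth_max Trait depth range in metres, or `NA`.
#' @param records Occurrence tibble (needed when the depth range is missing).
#' @param bathymetry Depth matrix (m, positive down) on `grid`.
#' @param grid An [sdm_grid()].
#' @param buffer_m Pelagic-path depth buffer, default 30 m.
#' @param occ_share Minimum record share for the occurrence-based path,
#'   default 0.1 (strict `>`).
#' @return Character vector of zone names (never empty).
#' @export
classify_vertical <- function(bottom_class, depth_min = NA, depth_max = NA,
                              records = NULL, bathymetry = NULL, grid = NULL,
                              buffer_m = 30, occ_share = 0.1) {
  has_range <- !is.na(depth_min) && !is.na(depth_max)
  if (has_range && depth_min > depth_max) {
    stop("depth_min exceeds depth_max", call. = FALSE)
  }
  if (bottom_class == "pelagic") {
    zones <- pelagic_zones()
    if (has_range) {
      return(zones_overlapping(zones, max(0, depth_min - buffer_m),
                               depth_max + buffer_m))
    }
    depths <- record_depths(records, bathymetry, grid)
    if (length(depths) == 0) {
      stop("pelagic species with no depth range and no usable occurrences",
           call. = FALSE)
    }
    return(zones_by_share(zones, depths, occ_share))
  }
  zones <- benthic_zones()
  if (has_range) {
    return(zones_overlapping(zones, depth_min, depth_max))
  }
  depths <- record_depths(records, bathymetry, grid)
  if (length(depths) == 0) {
    stop("no depth range and no usable occurrences for vertical classification",
         call. = FALSE)
  }
  zones_by_share(zones, depths, occ_share)
}

record_depths <- function(records, bathymetry, grid) {
  if (is.null(records) || is.null(bathymetry) || is.null(grid)) {
    return(numeric(0))
  }
  records <- as_occurrence_tbl(records)
  valid <- records[is.na(records$flag) | records$flag != 0L, , drop = FALSE]
  idx <- cell_of(grid, valid$lon, valid$lat)
  ok <- !is.na(idx$cell)
  d <- bathymetry[cbind(idx$row[ok], idx$col[ok])]
  d[!is.na(d)]
}

zones_by_share <- function(zones, depths, occ_share) {
  share <- vapply(seq_len(nrow(zones)), function(i) {
    mean(depths >= zones$lower[i] & depths < zones$upper[i])
  }, numeric(1))
  # hadal/bathypelagic upper bound is Inf so the half-open test covers all
  keep <- zones$zone[share > occ_share]
  if (length(keep) == 0) keep <- zones$zone[which.max(share)]
  keep
}

#' Build a species habitat profile
#'
#' Convenience wrapper assembling the three-axis classification into one
#' profile row.
#'
#' @param taxon_id Species identifier.
#' @param habitat_label Habitat vocabulary string.
#' @param depth_min,depth_max Trait depth range (m) or `NA`.
#' @param records Cleaned occurrence tibble.
#' @param coastal_mask,bathymetry,grid World context (see
#'   [classify_coast()], [classify_vertical()]).
#' @return One-row tibble: `taxon_id`, `habitat_label`, `depth_min`,
#'   `depth_max`, `bottom_class`, `coast_class`, `coastal_share`,
#'   `vertical_classes` (list-column).
#' @export
species_profile <- function(taxon_id, habitat_label,
                            depth_min = NA, depth_max = NA,
                            records = NULL, coastal_mask = NULL,
                            bathymetry = NULL, grid = NULL) {
  bottom <- classify_bottom(habitat_label)
  coast <- if (!is.null(records) && !is.null(coastal_mask)) {
    classify_coast(records, coastal_mask, grid)
  } else {
    list(coast_class = NA_character_, p = NA_real_)
  }
  vert <- classify_vertical(bottom, depth_min, depth_max,
                            records, bathymetry, grid)
  tibble::tibble(
    taxon_id = taxon_id,
    habitat_label = tolower(habitat_label),
    depth_min = depth_min, depth_max = depth_max,
    bottom_class = bottom,
    coast_class = coast$coast_class,
    coastal_share = coast$p,
    vertical_classes = list(vert)
  )
}
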