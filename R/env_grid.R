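#' Resolution selection rule
#'
#' Picks the working resolution from the share of ocean cells the modelled
#' region occupies: up to one third of the global ocean runs at 0.05 deg,
#' between one and two thirds at 0.1 deg, above two thirds at 0.2 deg.
#'
#' @param region_cell_count Ocean cells in the modelled region.
#' @param global_cell_count Ocean cells in the global grid.
#' @return Resolution in degrees: 0.05, 0.1 or 0.2.
#' @export
choose_resolution <- function(region_cell_count, global_cell_count) {
  if (global_cell_count <= 0) stop("global cell count must be positive",
                                   call. = FALSE)
  if (region_cell_count < 0 || region_cell_count > global_cell_count) {
    stop("region cell count must lie in [0, global]", call. = FALSE)
  }
  p <- region_cell_count / global_cell_count
  if (p <= 1 / 3) 0.05 else if (p <= 2 / 3) 0.1 else 0.2
}

aggregate_matrix <- function(m, f) {
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    block <- m[((i - 1) * f + 1):(i * f), , drop = FALSE]
    # block mean over ocean (non-NA) cells; all-NA blocks stay NA
    out[i, ] <- vapply(seq_len(nc), function(j) {
      vals <- block[, ((j - 1) * f + 1):(j * f)]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1))
  }
  out
}

bilinear_resample <- function(m, src_lon, src_lat, dst_lon, dst_lat) {
  # clamp target coordinates into the source cell-centre hull
  fx <- approx(src_lon, seq_along(src_lon), xout = pmin(pmax(dst_lon,
               src_lon[1]), src_lon[length(src_lon)]))$y
  fy <- approx(src_lat, seq_along(src_lat), xout = pmin(pmax(dst_lat,
               src_lat[1]), src_lat[length(src_lat)]))$y
  x0 <- pmin(floor(fx), length(src_lon) - 1L); wx <- fx - x0
  y0 <- pmin(floor(fy), length(src_lat) - 1L); wy <- fy - y0
  out <- matrix(NA_real_, length(dst_lat), length(dst_lon))
  for (j in seq_along(dst_lon)) {
    c0 <- x0[j]; w <- wx[j]
    col <- m[y0, c0] * (1 - w) + m[y0, c0 + 1] * w
    colp <- m[y0 + 1, c0] * (1 - w) + m[y0 + 1, c0 + 1] * w
    out[, j] <- col * (1 - wy) + colp * wy
  }
  out
}

#' Aggregate or disaggregate an environmental stack
#'
#' Aggregation (to a coarser resolution, integer factor) takes block means
#' over ocean cells; disaggregation (back to a finer resolution) uses
#' bilinear interpolation between coarse cell centres, with the fine ocean
#' mask re-imposed.
#'
#' @param stack An [env_stack()].
#' @param target_res Target resolution in degrees; must be an integer
#'   multiple or divisor of the stack resolution.
#' @param fine_ocean Optional logical ocean mask at the target resolution
#'   (required for disaggregation; defaults to bilinear support of the
#'   coarse mask).
#' @return A new `env_stack` at `target_res`.
#' @export
regrid <- function(stack, target_res, fine_ocean = NULL) {
  res <- stack$grid$res
  if (isTRUE(all.equal(target_res, res))) return(stack)
  if (target_res > res) {
    f <- target_res / res
    if (abs(f - round(f)) > 1e-8) {
      stop("aggregation factor must be an integer", call. = FALSE)
    }
    f <- as.integer(round(f))
    g2 <- sdm_grid(stack$grid$extent, target_res)
    layers <- lapply(stack$layers, aggregate_matrix, f = f)
    ocean2 <- aggregate_matrix(matrix(as.numeric(stack$ocean),
                                      nrow(stack$ocean)), f) > 0
    ocean2[is.na(ocean2)] <- FALSE
    return(env_stack(g2, layers, ocean2, stack$period, stack$scenario,
                     stack$stratum))
  }
  f <- res / target_res
  if (abs(f - round(f)) > 1e-8) {
    stop("disaggregation factor must be an integer", call. = FALSE)
  }
  g2 <- sdm_grid(stack$grid$extent, target_res)
  layers <- lapply(stack$layers, function(m) {
    filled <- fill_nearest(m)
    bilinear_resample(filled, stack$grid$lon, stack$grid$lat, g2$lon, g2$lat)
  })
  if (is.null(fine_ocean)) {
    om <- matrix(as.numeric(stack$ocean), nrow(stack$ocean))
    fine_ocean <- bilinear_resample(om, stack$grid$lon, stack$grid$lat,
                                    g2$lon, g2$lat) > 0
  }
  env_stack(g2, layers, fine_ocean, stack$period, stack$scenario,
            stack$stratum)
}

# fill NA cells from nearest non-NA neighbours (iterative 1-cell spread) so
# bilinear interpolation near coasts has support; re-masked afterwards
fill_nearest <- function(m) {
  while (anyNA(m) && !all(is.na(m))) {
    na <- is.na(m)
    shifted <- list(
      rbind(m[-1, , drop = FALSE], NA),
      rbind(NA, m[-nrow(m), , drop = FALSE]),
      cbind(m[, -1, drop = FALSE], NA),
      cbind(NA, m[, -ncol(m), drop = FALSE])
    )
    s <- Reduce(function(a, b) {
      out <- a
      take <- is.na(a) & !is.na(b)
      out[take] <- b[take]
      out
    }, shifted)
    cnt <- Reduce(`+`, lapply(shifted, function(x) !is.na(x)))
    avg <- Reduce(`+`, lapply(shifted, function(x) {
      x[is.na(x)] <- 0; x
    })) / pmax(cnt, 1)
    fillable <- na & cnt > 0
    if (!any(fillable)) break
    m[fillable] <- avg[fillable]
  }
  m
}

#' Default environmental binning scheme
#'
#' Bin sizes defining "unique environments": dissolved oxygen 10 mmol m-3,
#' temperature 0.05 degC, pH 0.1, primary productivity 0.5 mmol m-3,
#' salinity 0.1 psu, water velocity 0.02 m s-1, depth 5 m.
#'
#' @return Named numeric vector of bin sizes.
#' @export
default_binning_scheme <- function() {
  c(
    dissolved_oxygen = 10, temperature = 0.05, ph = 0.1,
    primary_productivity = 0.5, salinity = 0.1,
    water_velocity = 0.02, depth = 5
  )
}

snap_to_bin <- function(x, bin, mode = c("nearest", "floor")) {
  mode <- match.arg(mode)
  if (mode == "nearest") round(x / bin) * bin else floor(x / bin) * bin
}

#' Bin the environment into unique-environment keys
#'
#' Snaps each layer to the nearest multiple of its bin size and keys each
#' ocean cell by the tuple of snapped values: cells with equal tuples share a
#' key.
#'
#' @param stack An [env_stack()].
#' @param scheme Named bin sizes covering every layer; default
#'   [default_binning_scheme()].
#' @param mode `"nearest"` (default) or `"floor"` snapping.
#' @return Character matrix of environment keys (`NA` off-ocean).
#' @export
bin_environment <- function(stack, scheme = default_binning_scheme(),
                            mode = c("nearest", "floor")) {
  mode <- match.arg(mode)
  missing <- setdiff(names(stack$layers), names(scheme))
  if (length(missing)) {
    stop("no bin size for layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  snapped <- lapply(names(stack$layers), function(nm) {
    snap_to_bin(stack$layers[[nm]], scheme[[nm]], mode)
  })
  key <- do.call(paste, c(lapply(snapped, function(m) {
    format(as.vector(m), trim = TRUE)
  }), sep = "|"))
  key <- matrix(key, nrow(stack$ocean))
  key[!stack$ocean] <- NA_character_
  key
}

#' Thin occurrences to one record per unique environment
#'
#' Each record maps to the unique-environment key of its grid cell; within
#' each key one record is drawn uniformly at random (seed-deterministic).
#'
#' @param records Occurrence tibble; all records must fall on keyed cells.
#' @param env_keys Character key matrix from [bin_environment()].
#' @param grid The stack's [sdm_grid()].
#' @param seed Integer seed.
#' @return Thinned tibble (original row order); the set of represented keys
#'   is unchanged.
#' @export
env_thin <- function(records, env_keys, grid, seed = 1L) {
  records <- as_occurrence_tbl(records)
  idx <- cell_of(grid, records$lon, records$lat)
  ok <- !is.na(idx$cell)
  key <- rep(NA_character_, nrow(records))
  key[ok] <- env_keys[cbind(idx$row[ok], idx$col[ok])]
  if (anyNA(key)) {
    stop("record(s) off-grid or on unkeyed cells at rows: ",
         paste(utils::head(which(is.na(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  pick <- with_seed(seed, {
    tapply(seq_len(nrow(records)), key, function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    })
  })
  records[sort(as.integer(pick)), , drop = FALSE]
}

#' Generate pseudo-occurrences inside an expert range map
#'
#' For species with an expert map but few records, samples additional
#' presence points from the map's cells: candidates are cells whose
#' bathymetric depth lies within the species depth range (all cells when the
#' range is missing); the sample size is `min(1000, floor(0.4 * candidates))`
#' without replacement. Cells already holding real occurrences can be
#' excluded so generated points stay additional.
#'
#' @param erm Logical matrix: expert range on `grid`.
#' @param bathymetry Depth matrix (m, positive down) on `grid`.
#' @param grid An [sdm_grid()].
#' @param depth_min,depth_max Species depth range (m) or `NA`.
#' @param seed Integer seed.
#' @param exclude Optional occurrence tibble whose cells are removed from
#'   the candidate set.
#' @param taxon_id Identifier stamped on the generated records.
#' @return Occurrence tibble of generated points (cell centres) with
#'   `basis_of_record = "erm_generated"` and `flag = 1`.
#' @export
generate_pseudo_occurrences <- function(erm, bathymetry, grid,
                                        depth_min = NA, depth_max = NA,
                                        seed = 1L, exclude = NULL,
                                        taxon_id = NA_character_) {
  cand <- erm
  if (!is.na(depth_min) && !is.na(depth_max)) {
    cand <- cand & !is.na(bathymetry) &
      bathymetry >= depth_min & bathymetry <= depth_max
  }
  if (!is.null(exclude) && nrow(exclude) > 0) {
    idx <- cell_of(grid, exclude$lon, exclude$lat)
    ok <- !is.na(idx$cell)
    cand[cbind(idx$row[ok], idx$col[ok])] <- FALSE
  }
  cells <- which(cand)
  if (length(cells) == 0) {
    stop("no candidate cells for pseudo-occurrence generation", call. = FALSE)
  }
  n <- min(1000L, as.integer(floor(0.4 * length(cells))))
  if (n == 0) {
    stop("candidate set too small to sample any pseudo-occurrence",
         call. = FALSE)
  }
  chosen <- with_seed(seed, sample(cells, n))
  nr <- length(grid$lat)
  row <- (chosen - 1L) %% nr + 1L
  col <- (chosen - 1L) %/% nr + 1L
  tibble::tibble(
    taxon_id = taxon_id,
    lon = grid$lon[col], lat = grid$lat[row],
    year = NA_integer_, month = NA_integer_,
    basis_of_record = "erm_generated",
    source = "synthetic", original_flags = "", flag = 1L
  )
}
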