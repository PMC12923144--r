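#' Project an ensemble onto an environmental stack
#'
#' Evaluates the retained ensemble runs on every ocean cell of the stack that
#' lies inside the potential range and assembles the suitability (mean),
#' committee-average, coefficient-of-variation and clamping rasters, tagged
#' with the stack's period and scenario.
#'
#' @param ensemble An `sdm_ensemble` from [build_ensemble()].
#' @param stack An [env_stack()] whose layers include every ensemble
#'   variable.
#' @param pr Logical potential-range mask on the stack grid.
#' @return A `projection_product`: list with matrices `hsi`, `committee`,
#'   `cv`, `clamping` (integer count of out-of-calibration variables) plus
#'   `grid`, `period`, `scenario`.
#' @export
project_ensemble <- function(ensemble, stack, pr) {
  missing <- setdiff(ensemble$variables, names(stack$layers))
  if (length(missing)) {
    stop("stack lacks layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  domain <- stack$ocean & pr
  cells <- which(domain)
  newdata <- as.data.frame(lapply(
    stack$layers[ensemble$variables], function(m) m[cells]
  ))
  pred <- predict(ensemble, newdata)
  blank <- matrix(NA_real_, nrow(domain), ncol(domain))
  hsi <- blank; hsi[cells] <- pred$mean
  committee <- blank; committee[cells] <- pred$committee
  cv <- blank; cv[cells] <- pred$cv
  clamp <- clamping_mask(stack, ensemble$calibration_ranges)
  clamp[!domain] <- NA_integer_
  structure(
    list(hsi = hsi, committee = committee, cv = cv, clamping = clamp,
         grid = stack$grid, pr = pr, period = stack$period,
         scenario = stack$scenario),
    class = "projection_product"
  )
}

#' @export
print.projection_product <- function(x, ...) {
  cat(sprintf(
    "<projection_product> %s/%s: %d projected cells, HSI [%.2f, %.2f]\n",
    x$period, x$scenario, sum(!is.na(x$hsi)),
    min(x$hsi, na.rm = TRUE), max(x$hsi, na.rm = TRUE)
  ))
  invisible(x)
}

#' Clamping mask: count of variables outside calibration range
#'
#' Flags extrapolation: for each cell, how many environmental variables fall
#' below the minimum or above the maximum of the values used to calibrate
#' the ensemble.
#'
#' @param stack An [env_stack()].
#' @param calibration_ranges Tibble `variable` / `min` / `max`.
#' @return Integer matrix (`NA` off-ocean).
#' @export
clamping_mask <- function(stack, calibration_ranges) {
  cnt <- matrix(0L, nrow(stack$ocean), ncol(stack$ocean))
  for (i in seq_len(nrow(calibration_ranges))) {
    v <- stack$layers[[calibration_ranges$variable[i]]]
    if (is.null(v)) {
      stop("stack lacks layer '", calibration_ranges$variable[i], "'",
           call. = FALSE)
    }
    cnt <- cnt + (v < calibration_ranges$min[i] |
                    v > calibration_ranges$max[i])
  }
  cnt[!stack$ocean] <- NA_integer_
  cnt
}

#' Binarise a suitability raster
#'
#' Presence where suitability is greater than or equal to the threshold.
#'
#' @param hsi Suitability matrix in `[0, 1]`.
#' @param threshold Threshold in `(0, 1)`.
#' @return Logical presence matrix (`NA` preserved).
#' @export
binarize <- function(hsi, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  hsi >= threshold
}

#' Ensemble-level binarisation threshold
#'
#' The mean of the retained runs' own TSS-maximising thresholds; used as the
#' default when converting ensemble suitability to presence/absence.
#'
#' @param ensemble An `sdm_ensemble`.
#' @return A threshold in `(0, 1)`.
#' @export
ensemble_threshold <- function(ensemble) {
  mean(ensemble$runs$threshold[ensemble$retained])
}

#' Invasion / extinction change indices
#'
#' Compares binary present and future maps inside the potential range:
#' invasion cells are suitable in the future but not now, extinction cells
#' the reverse. Percent area gained/lost is the spherical area of those
#' cells relative to the spherical area of the potential range.
#'
#' @param binary_present,binary_future Logical presence matrices on `grid`.
#' @param pr Logical potential-range mask.
#' @param grid An [sdm_grid()].
#' @return A list: `invasion`, `extinction` (logical matrices),
#'   `percent_area_gained`, `percent_area_lost`, `area_gained_km2`,
#'   `area_lost_km2`, `pr_area_km2`.
#' @export
change_indices <- function(binary_present, binary_future, pr, grid) {
  if (!all(dim(binary_present) == dim(binary_future)) ||
      !all(dim(binary_present) == grid_dim(grid))) {
    stop("present/future rasters and grid do not share dimensions",
         call. = FALSE)
  }
  p <- binary_present & pr
  f <- binary_future & pr
  p[is.na(p)] <- FALSE; f[is.na(f)] <- FALSE
  invasion <- f & !p
  extinction <- p & !f
  pr_area <- mask_area_km2(pr, grid)
  gained <- mask_area_km2(invasion, grid)
  lost <- mask_area_km2(extinction, grid)
  list(
    invasion = invasion, extinction = extinction,
    percent_area_gained = 100 * gained / pr_area,
    percent_area_lost = 100 * lost / pr_area,
    area_gained_km2 = gained, area_lost_km2 = lost,
    pr_area_km2 = pr_area
  )
}

#' Stack binary species maps into a richness raster
#'
#' @param binary_maps List of logical presence matrices on one grid.
#' @param normalize Also return richness scaled by its maximum.
#' @return A list: `richness` (integer matrix) and, when `normalize`,
#'   `normalized` in `[0, 1]`.
#' @export
stack_richness <- function(binary_maps, normalize = TRUE) {
  if (length(binary_maps) == 0) stop("no species maps supplied", call. = FALSE)
  dims <- dim(binary_maps[[1]])
  for (m in binary_maps) {
    if (!all(dim(m) == dims)) stop("maps must share one grid", call. = FALSE)
  }
  rich <- Reduce(`+`, lapply(binary_maps, function(m) {
    m[is.na(m)] <- FALSE
    matrix(as.integer(m), dims[1], dims[2])
  }))
  out <- list(richness = rich)
  if (normalize) {
    mx <- max(rich)
    out$normalized <- if (mx > 0) rich / mx else rich
  }
  out
}

#' Resample a raster to a coarser grid by block maximum
#'
#' Used when comparing richness against coarser external datasets.
#'
#' @param m Numeric matrix.
#' @param factor Integer aggregation factor.
#' @return Matrix of per-block maxima.
#' @export
resample_max <- function(m, factor) {
  f <- as.integer(factor)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    block <- m[((i - 1) * f + 1):(i * f), , drop = FALSE]
    out[i, ] <- vapply(seq_len(nc), function(j) {
      vals <- block[, ((j - 1) * f + 1):(j * f)]
      if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }, numeric(1))
  }
  out
}
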