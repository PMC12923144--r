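#' Tidy the run ledger of an ensemble
#'
#' One row per modelling run with its cross-validation scheme, held-out
#' metrics, binarisation threshold and retention status.
#'
#' @param x An `sdm_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  x$runs |>
    dplyr::mutate(retained = dplyr::row_number() %in% x$retained) |>
    dplyr::select("algorithm", "scheme", "fold", "tss", "auc", "csi",
                  "threshold", "failed", "retained")
}

#' One-row ensemble summary
#'
#' @param x An `sdm_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: run counts, retention, mean metrics of the
#'   retained runs.
#' @export
glance.sdm_ensemble <- function(x, ...) {
  kept <- x$runs[x$retained, ]
  tibble::tibble(
    n_runs = nrow(x$runs),
    n_failed = sum(x$runs$failed),
    n_retained = length(x$retained),
    tss_gate = x$tss_gate,
    mean_tss = mean(kept$tss),
    mean_auc = mean(kept$auc),
    mean_csi = mean(kept$csi)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an environmental layer
#'
#' @param object An [env_stack()].
#' @param layer Layer name, default the first.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.env_stack <- function(object, layer = names(object$layers)[1], ...) {
  df <- raster_tbl(object$layers[[layer]], object$grid, "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s (%s, %s)", layer, object$period, object$scenario),
      x = "longitude", y = "latitude"
    )
}

#' Plot a projection product
#'
#' @param object A `projection_product`.
#' @param what One of `"hsi"`, `"committee"`, `"cv"`, `"clamping"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.projection_product <- function(object, what = "hsi", ...) {
  what <- match.arg(what, c("hsi", "committee", "cv", "clamping"))
  df <- raster_tbl(object[[what]], object$grid, what)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s (%s, %s)", what, object$period, object$scenario),
      x = "longitude", y = "latitude"
    )
}

#' Plot a range set
#'
#' Potential range in light blue, biogeographical range overlaid in dark
#' blue.
#'
#' @param object A [range_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.range_set <- function(object, ...) {
  pr <- raster_tbl(ifelse(object$pr, 1, NA), object$grid, "v")
  br <- raster_tbl(ifelse(object$br, 1, NA), object$grid, "v")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(data = pr, fill = "#9ecae1") +
    ggplot2::geom_raster(data = br, fill = "#2171b5") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Range (%s): BR %.0f km2, PR %.0f km2",
                      object$provenance, object$area_km2["br"],
                      object$area_km2["pr"]),
      x = "longitude", y = "latitude"
    )
}
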