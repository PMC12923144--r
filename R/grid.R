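#' Regular longitude/latitude grid
#'
#' A minimal description of a regular geographic grid: cell-centre coordinate
#' vectors plus the cell size in degrees. All raster-like objects in the
#' package (environmental stacks, range masks, partitions) live on an
#' `sdm_grid`. Matrices are indexed `[lat, lon]` with latitude ascending.
#'
#' @param extent Numeric length-4: `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param res Cell size in decimal degrees.
#' @return An object of class `sdm_grid` with elements `lon`, `lat`
#'   (cell-centre vectors), `res` and `extent`.
#' @export
sdm_grid <- function(extent, res) {
  stopifnot(length(extent) == 4, res > 0)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("degenerate extent: max must exceed min on both axes", call. = FALSE)
  }
  lon <- seq(extent[1] + res / 2, extent[2] - res / 2, by = res)
  lat <- seq(extent[3] + res / 2, extent[4] - res / 2, by = res)
  structure(
    list(lon = lon, lat = lat, res = res, extent = extent),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf(
    "<sdm_grid> %d x %d cells at %.3f deg, lon [%g, %g], lat [%g, %g]\n",
    length(x$lat), length(x$lon), x$res,
    x$extent[1], x$extent[2], x$extent[3], x$extent[4]
  ))
  invisible(x)
}

grid_dim <- function(grid) c(length(grid$lat), length(grid$lon))

same_grid <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) && isTRUE(all.equal(a$res, b$res)) &&
    isTRUE(all.equal(a$extent, b$extent))
}

#' Locate points on a grid
#'
#' Maps coordinates to row (latitude) and column (longitude) indices of the
#' grid cell containing each point. Points outside the grid extent get `NA`.
#'
#' @param grid An [sdm_grid()].
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return A list with integer vectors `row`, `col` and `cell`
#'   (single linear index, `NA` off-grid).
#' @export
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$extent[1]) / grid$res) + 1L
  row <- floor((lat - grid$extent[3]) / grid$res) + 1L
  nl <- length(grid$lon); nr <- length(grid$lat)
  # points exactly on the max edge belong to the last cell
  col[lon == grid$extent[2]] <- nl
  row[lat == grid$extent[4]] <- nr
  bad <- col < 1L | col > nl | row < 1L | row > nr |
    is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col, cell = (col - 1L) * nr + row)
}

#' Per-row spherical cell areas
#'
#' Area of one grid cell in each latitude row, on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))` with angles in radians.
#'
#' @param grid An [sdm_grid()].
#' @return Numeric vector (km^2), one value per latitude row.
#' @export
cell_area_km2 <- function(grid) {
  R <- 6371
  phi1 <- (grid$lat - grid$res / 2) * pi / 180
  phi2 <- (grid$lat + grid$res / 2) * pi / 180
  R^2 * (grid$res * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Spherical area of a raster mask
#'
#' @param mask Logical matrix on `grid` (`[lat, lon]`).
#' @param grid An [sdm_grid()].
#' @return Total area (km^2) of `TRUE` cells.
#' @export
mask_area_km2 <- function(mask, grid) {
  stopifnot(all(dim(mask) == grid_dim(grid)))
  sum(rowSums(mask, na.rm = TRUE) * cell_area_km2(grid))
}

# Binary dilation with a (2k+1)^2 square structuring element (Chebyshev ball),
# via a separable box filter on the 0/1 matrix. Degree buffers of the range
# builder reduce to this with k = round(deg / res).
dilate_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- box_any(m, k, margin = 1)
  m <- box_any(m, k, margin = 2)
  m > 0
}

# running "any nonzero in a +/-k window" along one margin, via cumsum
box_any <- function(m, k, margin) {
  if (margin == 2) return(t(box_any(t(m), k, margin = 1)))
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + k, n) + 1L
  lo <- pmax(seq_len(n) - k, 1L)
  cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
}

# Connected region of `domain` reachable from `seed` (8-connectivity),
# by iterated one-cell dilation until a fixed point. Used for same-ocean-basin
# masks: seed = range cells, domain = ocean.
grow_region <- function(seed, domain) {
  cur <- seed & domain
  if (!any(cur)) return(cur)
  repeat {
    nxt <- dilate_mask(cur, 1L) & domain
    if (sum(nxt) == sum(cur)) return(nxt)
    cur <- nxt
  }
}

#' Convert a raster-like matrix to a tibble
#'
#' Long-format bridge from the package's matrix rasters to tidy tools:
#' one row per grid cell with `lon`, `lat` and `value`.
#'
#' @param x Matrix on `grid`.
#' @param grid An [sdm_grid()].
#' @param name Column name for the cell value.
#' @param drop_na Drop cells with missing values (default `TRUE`).
#' @return A tibble with columns `lon`, `lat`, `<name>`.
#' @export
raster_tbl <- function(x, grid, name = "value", drop_na = TRUE) {
  out <- tibble::tibble(
    lon = rep(grid$lon, each = length(grid$lat)),
    lat = rep(grid$lat, times = length(grid$lon)),
    value = as.vector(x)
  )
  names(out)[3] <- name
  if (drop_na) out <- out[!is.na(out[[3]]), ]
  out
}

#' Environmental raster stack
#'
#' Named environmental layers sharing one grid and one ocean mask, tagged
#' with period and scenario. Layer names follow the modelling vocabulary:
#' `dissolved_oxygen` (mmol m-3), `temperature` (degC), `ph`,
#' `primary_productivity` (mmol m-3), `salinity` (psu), `water_velocity`
#' (m s-1), `depth` (m).
#'
#' @param grid An [sdm_grid()].
#' @param layers Named list of numeric matrices (`[lat, lon]`), `NA` on land.
#' @param ocean Logical matrix marking ocean cells.
#' @param period One of `"2000s"`, `"2050s"`, `"2090s"`.
#' @param scenario One of `"present"`, `"ssp126"`, `"ssp245"`, `"ssp585"`.
#' @param stratum `"surface"` or `"benthic"`.
#' @return An `env_stack` object.
#' @export
env_stack <- function(grid, layers, ocean,
                      period = "2000s", scenario = "present",
                      stratum = "surface") {
  stopifnot(is.list(layers), !is.null(names(layers)))
  period <- match.arg(period, c("2000s", "2050s", "2090s"))
  scenario <- match.arg(scenario, c("present", "ssp126", "ssp245", "ssp585"))
  stratum <- match.arg(stratum, c("surface", "benthic"))
  dims <- grid_dim(grid)
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == dims)) {
      stop("layer '", nm, "' does not match the grid dimensions", call. = FALSE)
    }
  }
  stopifnot(all(dim(ocean) == dims))
  # enforce a shared missing-value mask: layers defined exactly on ocean cells
  layers <- lapply(layers, function(m) { m[!ocean] <- NA_real_; m })
  structure(
    list(grid = grid, layers = layers, ocean = ocean,
         period = period, scenario = scenario, stratum = stratum),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "<env_stack> %s/%s [%s], %d layers (%s), %d ocean cells\n",
    x$period, x$scenario, x$stratum, length(x$layers),
    paste(names(x$layers), collapse = ", "), sum(x$ocean)
  ))
  invisible(x)
}

#' @describeIn env_stack Long-format tibble of all layers (ocean cells only).
#' @param x,... Method arguments.
#' @importFrom tibble as_tibble
#' @method as_tibble env_stack
#' @export
as_tibble.env_stack <- function(x, ...) {
  out <- raster_tbl(x$layers[[1]], x$grid, names(x$layers)[1], drop_na = FALSE)
  for (nm in names(x$layers)[-1]) {
    out[[nm]] <- as.vector(x$layers[[nm]])
  }
  out$ocean <- as.vector(x$ocean)
  out <- out[out$ocean, setdiff(names(out), "ocean")]
  tibble::as_tibble(out)
}

# Extract layer values at point locations; returns tibble with one column per
# layer plus .row/.col/.cell. Off-grid or land points yield NA rows.
env_at <- function(stack, lon, lat) {
  idx <- cell_of(stack$grid, lon, lat)
  out <- tibble::tibble(.row = idx$row, .col = idx$col, .cell = idx$cell)
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(idx$cell)
    v[ok] <- stack$layers[[nm]][cbind(idx$row[ok], idx$col[ok])]
    out[[nm]] <- v
  }
  out
}
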