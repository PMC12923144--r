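#' Great-circle distance (haversine)
#'
#' Pairwise-vectorised haversine distance on a sphere of radius 6371 km.
#' Arguments recycle as usual.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# distance from each point in (lon, lat) to its nearest neighbour in
# (plon, plat); chunked to bound memory on large candidate sets
nearest_presence_km <- function(lon, lat, plon, plat, chunk = 2048L) {
  n <- length(lon)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    d <- outer(seq_along(idx), seq_along(plon), function(i, j) {
      haversine_km(lon[idx[i]], lat[idx[i]], plon[j], plat[j])
    })
    out[idx] <- apply(d, 1, min)
  }
  out
}

# round-half-even to `digits` decimals (base R round() is already half-even)
round_half_even <- function(x, digits = 4) round(x, digits)

# seed helper: run `expr` under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
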