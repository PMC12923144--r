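#' Fit a surface range envelope
#'
#' Per-variable 2.5-97.5 percentile bounds of the presence environments
#' (linear-interpolation percentiles).
#'
#' @param presence_env Data frame / matrix of environment values at presence
#'   cells (one column per modelling variable).
#' @param probs Lower/upper percentile pair, default `c(0.025, 0.975)`.
#' @return Tibble with columns `variable`, `lower`, `upper`.
#' @export
fit_envelope <- function(presence_env, probs = c(0.025, 0.975)) {
  presence_env <- as.data.frame(presence_env)
  if (nrow(presence_env) < 2) {
    stop("need at least two presences to fit an envelope", call. = FALSE)
  }
  out <- purrr::map_dfr(names(presence_env), function(nm) {
    q <- stats::quantile(presence_env[[nm]], probs = probs, na.rm = TRUE,
                         names = FALSE, type = 7)
    tibble::tibble(variable = nm, lower = q[1], upper = q[2])
  })
  degen <- out$variable[out$lower == out$upper]
  if (length(degen)) {
    warning("degenerate envelope (constant variable): ",
            paste(degen, collapse = ", "), call. = FALSE)
  }
  out
}

# logical matrix stack predicate: per cell, count of variables outside their
# envelope interval
count_outside_envelope <- function(stack, envelope) {
  cnt <- matrix(0L, nrow(stack$ocean), ncol(stack$ocean))
  for (i in seq_len(nrow(envelope))) {
    v <- stack$layers[[envelope$variable[i]]]
    if (is.null(v)) {
      stop("stack lacks envelope variable '", envelope$variable[i], "'",
           call. = FALSE)
    }
    cnt <- cnt + (v < envelope$lower[i] | v > envelope$upper[i])
  }
  cnt
}

sample_cells <- function(eligible, grid, n, seed) {
  cells <- which(eligible)
  if (length(cells) < n) {
    stop("only ", length(cells), " eligible cells for ", n,
         " pseudo-absences", call. = FALSE)
  }
  chosen <- with_seed(seed, sample(cells, n))
  nr <- length(grid$lat)
  tibble::tibble(
    lon = grid$lon[(chosen - 1L) %/% nr + 1L],
    lat = grid$lat[(chosen - 1L) %% nr + 1L]
  )
}

#' Pseudo-absences by the surface range envelope rule
#'
#' For pelagic species: candidate cells are ocean cells inside the potential
#' range where **all** modelling variables fall outside their envelope
#' interval; `n` cells are drawn uniformly without replacement. When the
#' strict rule yields fewer than `n` cells the predicate is relaxed to "any
#' variable outside" with a warning.
#'
#' @param stack An [env_stack()].
#' @param envelope Envelope tibble from [fit_envelope()].
#' @param pr Logical potential-range mask on the stack grid.
#' @param n Number of pseudo-absences.
#' @param seed Integer seed.
#' @return Tibble of points (`lon`, `lat`, `role = "pseudo_absence"`);
#'   attribute `relaxed` says whether the fallback rule fired.
#' @export
sample_pa_sre <- function(stack, envelope, pr, n, seed = 1L) {
  outside <- count_outside_envelope(stack, envelope)
  nvar <- nrow(envelope)
  strict <- stack$ocean & pr & !is.na(outside) & outside == nvar
  relaxed <- FALSE
  eligible <- strict
  if (sum(eligible, na.rm = TRUE) < n) {
    relaxed <- TRUE
    warning("fewer than n cells satisfy the strict all-variables-outside ",
            "rule; relaxing to any-variable-outside", call. = FALSE)
    eligible <- stack$ocean & pr & !is.na(outside) & outside >= 1L
  }
  pts <- sample_cells(eligible, stack$grid, n, seed)
  pts$role <- "pseudo_absence"
  attr(pts, "relaxed") <- relaxed
  pts
}

#' Pseudo-absences by the disk (exclusion ring) rule
#'
#' For benthic/demersal species: candidate cells are ocean cells inside the
#' potential range whose great-circle distance to the nearest presence lies
#' between `min_km` and `max_km`; `n` cells are drawn uniformly without
#' replacement.
#'
#' @param presences Tibble with `lon`, `lat` of presences.
#' @param pr Logical potential-range mask.
#' @param ocean Logical ocean mask.
#' @param grid An [sdm_grid()].
#' @param n Number of pseudo-absences.
#' @param min_km,max_km Ring bounds, defaults 80 and 1000 km.
#' @param seed Integer seed.
#' @return Tibble of points (`lon`, `lat`, `role = "pseudo_absence"`).
#' @export
sample_pa_disk <- function(presences, pr, ocean, grid, n,
                           min_km = 80, max_km = 1000, seed = 1L) {
  if (nrow(presences) == 0) stop("no presences supplied", call. = FALSE)
  cand <- which(pr & ocean)
  if (length(cand) == 0) stop("potential range holds no ocean cells",
                              call. = FALSE)
  nr <- length(grid$lat)
  clon <- grid$lon[(cand - 1L) %/% nr + 1L]
  clat <- grid$lat[(cand - 1L) %% nr + 1L]
  dmin <- nearest_presence_km(clon, clat, presences$lon, presences$lat)
  ok <- dmin >= min_km & dmin <= max_km
  if (sum(ok) < n) {
    stop("only ", sum(ok), " cells lie in the ", min_km, "-", max_km,
         " km ring; cannot draw ", n, " pseudo-absences", call. = FALSE)
  }
  chosen <- with_seed(seed, sample(which(ok), n))
  tibble::tibble(lon = clon[chosen], lat = clat[chosen],
                 role = "pseudo_absence")
}
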