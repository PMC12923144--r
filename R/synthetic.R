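#' Synthetic ocean worlds
#'
#' Self-contained worlds with a land mass, offshore-deepening bathymetry,
#' smooth environmental gradients plus seeded noise, latitudinal
#' biogeographic provinces with an Arctic subdivision, and scenario deltas
#' for future periods. Every pipeline stage can run against these with known
#' ground truth.
#'
#' @name synthetic-world
NULL

smooth_noise <- function(nr, nc, sd = 1, passes = 3) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    m <- (m +
            rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE]) +
            rbind(m[1, , drop = FALSE], m[-nr, , drop = FALSE]) +
            cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE]) +
            cbind(m[, 1, drop = FALSE], m[, -nc, drop = FALSE])) / 5
  }
  m / stats::sd(m) * sd
}

#' Generate a synthetic world
#'
#' The western margin of the extent is a continent with a sinuous coastline;
#' bathymetry deepens with distance from the coast; surface temperature
#' follows a latitudinal gradient with seeded smooth noise; the remaining
#' layers are simple functions of temperature, latitude and depth plus
#' noise. Provinces are latitudinal bands; the northernmost band is the
#' Arctic province, subdivided longitudinally into finer Arctic units; depth
#' zones cut bathymetry at 800 / 3500 / 6500 m.
#'
#' @param extent Lon/lat box, default `c(-30, 30, -40, 40)`.
#' @param res Resolution in degrees (0.05, 0.1 or 0.2), default 0.2.
#' @param n_provinces Number of latitudinal province bands, default 5.
#' @param deltas Named per-layer additive change reaching the future stacks
#'   at scenario/period multiplier 1, default `c(temperature = 2)`.
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return A `synthetic_world`: grid, land/ocean masks, `bathymetry`,
#'   `surface` and `benthic` present-day [env_stack()]s, a
#'   [bio_partition()], the `deltas`, and the seed.
#' @export
make_world <- function(extent = c(-30, 30, -40, 40), res = 0.2,
                       n_provinces = 5, deltas = c(temperature = 2),
                       seed = 1L) {
  if (!res %in% c(0.05, 0.1, 0.2)) {
    stop("resolution must be one of 0.05, 0.1, 0.2", call. = FALSE)
  }
  grid <- sdm_grid(extent, res)
  nr <- length(grid$lat); nc <- length(grid$lon)
  lat_m <- matrix(grid$lat, nr, nc)
  lon_m <- matrix(grid$lon, nr, nc, byrow = TRUE)
  lat_span <- extent[4] - extent[3]
  lon_span <- extent[2] - extent[1]

  with_seed(seed, {
    # coastline: continent occupies the west, coast longitude wiggles with
    # latitude
    coast_lon <- extent[1] + 0.18 * lon_span +
      0.05 * lon_span * sin(2 * pi * (lat_m - extent[3]) / lat_span * 2)
    land <- lon_m <= coast_lon
    ocean <- !land

    # bathymetry: deepens with distance from the coast, mild noise
    off <- lon_m - coast_lon
    bathy <- pmax(0, off) * (5500 / (0.55 * lon_span)) +
      40 * abs(smooth_noise(nr, nc, sd = 1))
    bathy <- pmin(bathy, 7200)
    bathy[land] <- NA_real_

    sst <- 28 - 24 * (abs(lat_m) / max(abs(grid$lat)))^1.3 +
      smooth_noise(nr, nc, sd = 0.6)
    sal <- 35 + 1.2 * sin(lat_m / 12) + smooth_noise(nr, nc, sd = 0.15)
    oxy <- 320 - 3.5 * sst + smooth_noise(nr, nc, sd = 4)
    ph <- 8.15 - 0.004 * sst + smooth_noise(nr, nc, sd = 0.01)
    prod <- 4 + 2.5 * cos(lat_m / 14) + 2 * exp(-pmax(0, off) / 5) +
      smooth_noise(nr, nc, sd = 0.3)
    vel <- 0.12 + 0.1 * abs(sin(lat_m / 9)) +
      abs(smooth_noise(nr, nc, sd = 0.02))

    bt <- 3.5 + (sst - 3.5) * exp(-bathy / 900)
    boxy <- oxy - 40 * (1 - exp(-bathy / 1500))
    bprod <- prod * exp(-bathy / 2500)

    surface <- env_stack(
      grid,
      list(dissolved_oxygen = oxy, temperature = sst, ph = ph,
           primary_productivity = prod, salinity = sal,
           water_velocity = vel),
      ocean, period = "2000s", scenario = "present", stratum = "surface"
    )
    benthic <- env_stack(
      grid,
      list(dissolved_oxygen = boxy, temperature = bt,
           primary_productivity = bprod, salinity = sal,
           water_velocity = vel, depth = bathy),
      ocean, period = "2000s", scenario = "present", stratum = "benthic"
    )

    # provinces: latitudinal bands, the northernmost being the Arctic
    band <- pmin(n_provinces,
                 floor((lat_m - extent[3]) / (lat_span / n_provinces)) + 1)
    provinces <- matrix(as.integer(band), nr, nc)
    provinces[land] <- NA_integer_
    arctic_id <- n_provinces
    arctic_units <- matrix(
      as.integer(pmin(4, floor((lon_m - extent[1]) / (lon_span / 4)) + 1)),
      nr, nc
    )
    arctic_units[land | provinces != arctic_id] <- NA_integer_

    zones <- matrix(NA_integer_, nr, nc)
    zones[ocean] <- cut(bathy[ocean], c(-Inf, 800, 3500, 6500, Inf),
                        labels = FALSE)
    partition <- bio_partition(grid, provinces, zones, arctic_units,
                               arctic_province_id = arctic_id)

    structure(
      list(grid = grid, land = land, ocean = ocean, bathymetry = bathy,
           surface = surface, benthic = benthic, partition = partition,
           deltas = deltas, seed = seed),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d at %.2f deg, %.0f%% ocean, seed %d\n",
    length(x$grid$lat), length(x$grid$lon), x$grid$res,
    100 * mean(x$ocean), x$seed
  ))
  invisible(x)
}

#' Future environmental stack for a scenario and period
#'
#' Applies the world's per-layer deltas, scaled by scenario intensity
#' (ssp126 0.4, ssp245 0.7, ssp585 1) and period progression (2050s 0.5,
#' 2090s 1). Deltas are spatially uniform.
#'
#' @param world A [make_world()] result.
#' @param period `"2050s"` or `"2090s"`.
#' @param scenario `"ssp126"`, `"ssp245"` or `"ssp585"`.
#' @param stratum `"surface"` or `"benthic"`.
#' @return An [env_stack()].
#' @export
future_stack <- function(world, period = "2050s", scenario = "ssp585",
                         stratum = c("surface", "benthic")) {
  stratum <- match.arg(stratum)
  period <- match.arg(period, c("2050s", "2090s"))
  scenario <- match.arg(scenario, c("ssp126", "ssp245", "ssp585"))
  s_mult <- c(ssp126 = 0.4, ssp245 = 0.7, ssp585 = 1)[[scenario]]
  p_mult <- c(`2050s` = 0.5, `2090s` = 1)[[period]]
  base <- world[[stratum]]
  layers <- base$layers
  for (nm in intersect(names(world$deltas), names(layers))) {
    layers[[nm]] <- layers[[nm]] + world$deltas[[nm]] * s_mult * p_mult
  }
  env_stack(base$grid, layers, base$ocean, period, scenario, stratum)
}

#' Define a species with a known niche
#'
#' Suitability is a product of truncated-Gaussian kernels over the chosen
#' environmental variables, evaluated on the stratum matching the habitat
#' label; the true range is the set of ocean cells whose suitability exceeds
#' `cutoff`.
#'
#' @param world A [make_world()] result.
#' @param taxon_id Identifier string.
#' @param habitat_label Habitat vocabulary label (drives the stratum).
#' @param niche Tibble with `variable`, `centre`, `breadth`.
#' @param depth_min,depth_max Trait depth range (m) or `NA`.
#' @param cutoff True-range suitability cutoff, default 0.5.
#' @return A `true_species`: niche, suitability matrix, `true_range` mask,
#'   stratum and traits.
#' @export
make_species <- function(world, taxon_id, habitat_label, niche,
                         depth_min = NA, depth_max = NA, cutoff = 0.5) {
  bottom <- classify_bottom(habitat_label)
  stratum <- if (bottom == "pelagic") "surface" else "benthic"
  stack <- world[[stratum]]
  suit <- matrix(1, nrow(world$ocean), ncol(world$ocean))
  for (i in seq_len(nrow(niche))) {
    v <- stack$layers[[niche$variable[i]]]
    if (is.null(v)) {
      stop("stratum '", stratum, "' has no layer '", niche$variable[i], "'",
           call. = FALSE)
    }
    suit <- suit * exp(-0.5 * ((v - niche$centre[i]) / niche$breadth[i])^2)
  }
  suit[!world$ocean] <- NA_real_
  if (!is.na(depth_min) && !is.na(depth_max)) {
    ok <- !is.na(world$bathymetry) & world$bathymetry >= depth_min &
      world$bathymetry <= depth_max
    suit[!ok] <- 0
    suit[!world$ocean] <- NA_real_
  }
  true_range <- !is.na(suit) & suit > cutoff
  if (!any(true_range)) {
    stop("true range is empty: niche does not intersect this world",
         call. = FALSE)
  }
  structure(
    list(taxon_id = taxon_id, habitat_label = tolower(habitat_label),
         bottom_class = bottom, stratum = stratum, niche = niche,
         depth_min = depth_min, depth_max = depth_max,
         suitability = suit, true_range = true_range, cutoff = cutoff),
    class = "true_species"
  )
}

#' Sample error-injected occurrence records from a true species
#'
#' Draws `n` presence records with probability proportional to true
#' suitability (jittered within their cell), then injects synthetic error
#' records at the given rates: points on land, points at exactly (0, 0),
#' exact duplicates of clean records, and out-of-range strays placed on
#' ocean cells at least ~3 degrees outside the true range. Ground truth is
#' recorded in `is_error` / `error_kind` so recovery can be asserted.
#'
#' @param world A [make_world()] result.
#' @param species A [make_species()] result.
#' @param n Number of clean presence records.
#' @param error_profile Named rates: `land`, `zero`, `duplicate`, `stray`,
#'   `missing_date` (the last applies to clean records, it is not an error).
#' @param seed Integer seed.
#' @return Occurrence tibble with the standard columns plus `is_error`,
#'   `error_kind`.
#' @export
sample_occurrences <- function(world, species, n,
                               error_profile = list(land = 0.05, zero = 0.02,
                                                    duplicate = 0.05,
                                                    stray = 0.03,
                                                    missing_date = 0.1),
                               seed = 1L) {
  stopifnot(n > 0)
  grid <- world$grid
  nr <- length(grid$lat)
  with_seed(seed, {
    # clean presences realise the true range: cells above the suitability
    # cutoff, weighted by suitability
    cells <- which(species$true_range)
    draw <- sample(cells, n, replace = TRUE,
                   prob = species$suitability[cells])
    jit <- function(k) stats::runif(k, -grid$res / 2, grid$res / 2)
    mk <- function(cell, kind) {
      k <- length(cell)
      tibble::tibble(
        taxon_id = species$taxon_id,
        lon = grid$lon[(cell - 1L) %/% nr + 1L] + jit(k),
        lat = grid$lat[(cell - 1L) %% nr + 1L] + jit(k),
        year = sample(2000:2020, k, replace = TRUE),
        month = sample(1:12, k, replace = TRUE),
        basis_of_record = sample(c("observation", "specimen"), k,
                                 replace = TRUE, prob = c(0.8, 0.2)),
        source = sample(c("aquamaps", "obis", "gbif"), k, replace = TRUE),
        original_flags = "",
        flag = NA_integer_,
        is_error = kind != "none", error_kind = kind
      )
    }
    occ <- mk(draw, "none")
    occ$flag[occ$source == "aquamaps"] <- 1L
    md <- stats::runif(n) < (error_profile$missing_date %||% 0)
    occ$year[md] <- NA_integer_; occ$month[md] <- NA_integer_

    extras <- list()
    n_land <- stats::rbinom(1, n, error_profile$land %||% 0)
    if (n_land > 0) {
      land_cells <- which(world$land)
      extras$land <- mk(sample(land_cells, n_land, replace = TRUE), "land")
    }
    n_zero <- stats::rbinom(1, n, error_profile$zero %||% 0)
    if (n_zero > 0) {
      zero <- mk(rep(1L, n_zero), "zero_zero")
      zero$lon <- 0; zero$lat <- 0
      extras$zero <- zero
    }
    n_dup <- stats::rbinom(1, n, error_profile$duplicate %||% 0)
    if (n_dup > 0) {
      dup <- occ[sample.int(n, n_dup, replace = TRUE), , drop = FALSE]
      dup$is_error <- TRUE; dup$error_kind <- "duplicate"
      # duplicates carry less metadata so deduplication keeps the original
      dup$basis_of_record <- NA_character_
      dup$flag <- NA_integer_
      extras$dup <- dup
    }
    n_stray <- stats::rbinom(1, n, error_profile$stray %||% 0)
    if (n_stray > 0) {
      far <- world$ocean &
        !dilate_mask(species$true_range, ceiling(3 / grid$res))
      far_cells <- which(far)
      if (length(far_cells) > 0) {
        stray <- mk(sample(far_cells, n_stray, replace = TRUE), "stray")
        extras$stray <- stray
      }
    }
    out <- dplyr::bind_rows(c(list(occ), extras))
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Polygonise a species' true range into a synthetic expert map
#'
#' Returns the true-range mask, optionally eroded by a number of cells to
#' mimic an expert map that under-covers the realised distribution.
#'
#' @param species A [make_species()] result.
#' @param erode_cells Erosion radius in cells, default 0 (exact).
#' @return Logical matrix usable as the `erm` argument of
#'   [build_from_erm()].
#' @export
make_erm <- function(species, erode_cells = 0) {
  m <- species$true_range
  if (!any(m)) stop("species has an empty true range", call. = FALSE)
  if (erode_cells > 0) {
    m <- !dilate_mask(!m, as.integer(erode_cells))
    if (!any(m)) {
      stop("erosion removed the entire range", call. = FALSE)
    }
  }
  m
}
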