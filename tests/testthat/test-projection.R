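proj_fixture <- function() {
  grid <- sdm_grid(c(0, 10, 0, 10), 1)
  ocean <- matrix(TRUE, 10, 10)
  lat_m <- matrix(grid$lat, 10, 10)
  st <- env_stack(grid, list(temperature = 25 - lat_m,
                             salinity = matrix(35, 10, 10)), ocean)
  tr <- tibble::tibble(temperature = c(24, 22, 20, 18),
                       salinity = c(34, 35, 35, 36),
                       label = c(1L, 1L, 0L, 0L), weight = 1)
  attr(tr, "variables") <- c("temperature", "salinity")
  runs <- tibble::tibble(
    scheme = "s", fold = 1:2, algorithm = "stub",
    tss = c(0.8, 0.9), auc = 0.9, csi = 0.8, threshold = c(0.5, 0.5),
    sensitivity = 0.9, specificity = 0.9, failed = FALSE,
    message = NA_character_,
    model = list(
      list(predict = function(newX) pmin(pmax((newX$temperature - 15) / 10, 0), 1)),
      list(predict = function(newX) pmin(pmax((newX$temperature - 16) / 10, 0), 1))
    )
  )
  ens <- build_ensemble(runs, tr)
  list(grid = grid, stack = st, ens = ens, ocean = ocean)
}

test_that("projection fills exactly the potential range with [0,1] values", {
  fx <- proj_fixture()
  pr <- rect_mask(fx$grid, 0, 10, 0, 6)
  prod <- project_ensemble(fx$ens, fx$stack, pr)
  inside <- !is.na(prod$hsi)
  expect_identical(inside, pr & fx$ocean)
  expect_true(all(prod$hsi[inside] >= 0 & prod$hsi[inside] <= 1))
  expect_true(all(prod$committee[inside] %in% c(0, 0.5, 1)))
  expect_equal(prod$period, "2000s")
  bad_stack <- env_stack(fx$grid, list(ph = matrix(8, 10, 10)), fx$ocean)
  expect_error(project_ensemble(fx$ens, bad_stack, pr), "temperature")
})

test_that("future products carry their scenario tags", {
  fx <- proj_fixture()
  fut <- env_stack(fx$grid,
                   list(temperature = fx$stack$layers$temperature + 2,
                        salinity = fx$stack$layers$salinity),
                   fx$ocean, period = "2050s", scenario = "ssp585")
  prod <- project_ensemble(fx$ens, fut, matrix(TRUE, 10, 10))
  expect_equal(prod$period, "2050s")
  expect_equal(prod$scenario, "ssp585")
})

test_that("clamping counts variables outside the calibration range", {
  fx <- proj_fixture()
  calib <- fx$ens$calibration_ranges  # temperature [18,24], salinity [34,36]
  cm <- clamping_mask(fx$stack, calib)
  # direct count oracle per cell
  t_out <- fx$stack$layers$temperature < 18 | fx$stack$layers$temperature > 24
  s_out <- fx$stack$layers$salinity < 34 | fx$stack$layers$salinity > 36
  expect_equal(cm, t_out + s_out, ignore_attr = TRUE)
  # a stack entirely within calibration clamps nowhere
  ok_stack <- env_stack(fx$grid, list(temperature = matrix(20, 10, 10),
                                      salinity = matrix(35, 10, 10)),
                        fx$ocean)
  expect_true(all(clamping_mask(ok_stack, calib) == 0))
  # constructed exceedance: warming past the calibration maximum
  warm <- env_stack(fx$grid, list(temperature = matrix(30, 10, 10),
                                  salinity = matrix(35, 10, 10)), fx$ocean)
  expect_true(all(clamping_mask(warm, calib) >= 1))
})

test_that("binarisation is inclusive at the threshold and monotone", {
  hsi <- matrix(c(0.9, 0.3, 0.5, NA), 2, 2)
  b <- binarize(hsi, 0.5)
  expect_equal(b[1, 1], TRUE)
  expect_equal(b[2, 1], FALSE)
  expect_equal(b[1, 2], TRUE)     # boundary inclusive
  expect_true(is.na(b[2, 2]))
  areas <- vapply(seq(0.05, 0.95, 0.05), function(t) {
    sum(binarize(matrix(runif(100, 0, 1), 10), t))
  }, numeric(1))
  set.seed(1)
  m <- matrix(runif(400), 20)
  areas <- vapply(seq(0.05, 0.95, 0.05),
                  function(t) sum(binarize(m, t)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("change indices partition the potential range", {
  grid <- sdm_grid(c(0, 10, 0, 10), 1)
  pr <- matrix(TRUE, 10, 10)
  present <- rect_mask(grid, 0, 10, 0, 6)
  future <- rect_mask(grid, 0, 10, 2, 8)
  ch <- change_indices(present, future, pr, grid)
  expect_true(all(ch$invasion == (future & !present)))
  expect_true(all(ch$extinction == (present & !future)))
  expect_equal(sum(ch$invasion & ch$extinction), 0)
  # invasion/extinction/unchanged cells tile the pr
  unchanged <- (present & future) | (!present & !future)
  expect_true(all(ch$invasion | ch$extinction | unchanged))
  # identical maps: no change
  same <- change_indices(present, present, pr, grid)
  expect_equal(same$percent_area_gained, 0)
  expect_equal(same$percent_area_lost, 0)
  expect_error(change_indices(present, future[1:5, ], pr, grid), "dimensions")
})

test_that("area percentages agree with brute-force spherical summation", {
  grid <- sdm_grid(c(0, 10, 30, 40), 0.5)
  pr <- matrix(TRUE, length(grid$lat), length(grid$lon))
  present <- rect_mask(grid, 0, 10, 30, 35)
  future <- rect_mask(grid, 0, 10, 33, 38)
  ch <- change_indices(present, future, pr, grid)
  R <- 6371
  cell_area <- function(lat) {
    phi1 <- (lat - 0.25) * pi / 180; phi2 <- (lat + 0.25) * pi / 180
    R^2 * (0.5 * pi / 180) * (sin(phi2) - sin(phi1))
  }
  brute <- function(mask) {
    s <- 0
    for (i in seq_along(grid$lat)) for (j in seq_along(grid$lon)) {
      if (mask[i, j]) s <- s + cell_area(grid$lat[i])
    }
    s
  }
  expect_equal(ch$area_gained_km2, brute(ch$invasion), tolerance = 1e-6)
  expect_equal(ch$percent_area_lost,
               100 * brute(ch$extinction) / brute(pr), tolerance = 1e-6)
  # higher-latitude cells are smaller on the sphere
  expect_lt(cell_area(39), cell_area(31))
})

test_that("richness stacking sums presences and normalises to 1", {
  m1 <- rect_mask(ocean_grid, 0, 10, 0, 10)
  m2 <- rect_mask(ocean_grid, 5, 15, 5, 15)
  r <- stack_richness(list(m1, m2))
  expect_equal(max(r$richness), 2)
  overlap <- rect_mask(ocean_grid, 5, 10, 5, 10)
  expect_true(all(r$richness[overlap] == 2))
  expect_equal(max(r$normalized), 1)
  expect_true(all(r$normalized >= 0 & r$normalized <= 1))
  expect_error(stack_richness(list()), "no species")
  # coarser comparison grid by block maximum
  rm <- resample_max(r$richness, 2)
  expect_equal(dim(rm), dim(r$richness) / 2)
  expect_equal(max(rm), 2)
})
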