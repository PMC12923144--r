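test_that("expert-map buffering expands a rectangle by the buffer in degrees", {
  erm <- rect_mask(ocean_grid, 0, 10, 0, 10)
  rs <- build_from_erm(erm, ocean_grid, all_ocean)
  # degree-buffer oracle: a rectangle dilated by a square element is the
  # rectangle expanded by the buffer on each side
  expect_identical(rs$br, rect_mask(ocean_grid, -1, 11, -1, 11))
  expect_identical(rs$pr, rect_mask(ocean_grid, -10, 20, -10, 20))
  expect_true(all(rs$pr[rs$br]))
  expect_equal(rs$provenance, "erm")
})

test_that("ranges exclude land and stay in the source ocean basin", {
  grid <- ocean_grid
  land <- rect_mask(grid, 14, 16, -30, 40)  # meridional land barrier
  ocean <- !land
  erm <- rect_mask(grid, 0, 10, 0, 10)
  rs <- build_from_erm(erm, grid, ocean)
  expect_equal(sum(rs$br & land), 0)
  expect_equal(sum(rs$pr & land), 0)
  # the 10-degree buffer would cross the barrier; the basin mask stops it
  expect_equal(sum(rs$pr[, grid$lon > 16]), 0)
  expect_gt(sum(rs$pr[, grid$lon < 14]), 0)
  expect_error(build_from_erm(erm & FALSE, grid, ocean), "ocean")
})

test_that("occurrence bounding boxes span the surviving extremes", {
  occ <- occ_tbl(lon = c(5, 8, 20), lat = c(5, 2, 30),
                 flag = c(NA, NA, 0L))  # flagged-out stray ignored
  expect_equal(bounding_box_from_occurrences(occ), c(5, 8, 2, 5))
  one <- occ_tbl(3, 4)
  expect_equal(bounding_box_from_occurrences(one, res = 0.1),
               c(2.9, 3.1, 3.9, 4.1))
  expect_error(bounding_box_from_occurrences(occ_tbl(1, 1, flag = 0L)),
               "no surviving")
  expect_equal(merge_boxes(c(0, 5, 0, 5), c(-2, 3, 1, 9)), c(-2, 5, 0, 9))
})

test_that("thinning distance follows the record-count rule", {
  expect_equal(thin_distance_km(800), 0)
  expect_equal(thin_distance_km(1000), 0)
  expect_equal(thin_distance_km(1001), 20)
  expect_equal(thin_distance_km(2000), 20)
  expect_equal(thin_distance_km(5000), 20)
  expect_equal(thin_distance_km(6000), 30)
})

test_that("spatial thinning enforces the pairwise minimum distance", {
  close_pair <- occ_tbl(lon = c(10, 10.045), lat = c(0, 0))  # ~5 km apart
  out <- spatial_thin(close_pair, seed = 1, distance_km = 20)
  expect_equal(nrow(out), 1)
  set.seed(9)
  occ <- occ_tbl(lon = runif(200, 0, 5), lat = runif(200, 0, 5))
  thinned <- spatial_thin(occ, seed = 4, distance_km = 50)
  # brute-force pairwise great-circle check
  d <- outer(seq_len(nrow(thinned)), seq_len(nrow(thinned)), function(i, j) {
    haversine_km(thinned$lon[i], thinned$lat[i],
                 thinned$lon[j], thinned$lat[j])
  })
  expect_true(all(d[upper.tri(d)] >= 50))
  expect_identical(spatial_thin(occ, seed = 4, distance_km = 50), thinned)
  # n <= 1000 passes through untouched under the automatic rule
  expect_equal(nrow(spatial_thin(occ, seed = 1)), 200)
})

test_that("haversine agrees with an independent geodesic library", {
  skip_if_not_installed("geosphere")
  set.seed(3)
  lon <- runif(20, -180, 180); lat <- runif(20, -89, 89)
  ours <- haversine_km(lon[1:10], lat[1:10], lon[11:20], lat[11:20])
  ref <- geosphere::distHaversine(cbind(lon[1:10], lat[1:10]),
                                  cbind(lon[11:20], lat[11:20]),
                                  r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

# three-province partition with longitude bands on an all-ocean world
band_partition <- function(grid) {
  lon_m <- matrix(grid$lon, length(grid$lat), length(grid$lon), byrow = TRUE)
  prov <- matrix(1L, length(grid$lat), length(grid$lon))
  prov[lon_m > -7] <- 2L
  prov[lon_m > 16] <- 3L
  zones <- matrix(1L, length(grid$lat), length(grid$lon))
  zones[, grid$lon > 5] <- 2L   # east half deeper
  bio_partition(grid, prov, zones)
}

test_that("province filter keeps provinces above the share threshold", {
  part <- band_partition(ocean_grid)
  # 50 / 30 / 2 records in provinces 1 / 2 / 3: province 3 share 2.4% <= 3.3%
  occ <- occ_tbl(
    lon = c(runif(50, -25, -10), runif(30, -5, 10), runif(2, 20, 35)),
    lat = runif(82, -20, 20)
  )
  prof <- tibble::tibble(taxon_id = "sp", habitat_label = "pelagic",
                         bottom_class = "pelagic", coast_class = "oceanic")
  rs <- derive_range(occ, prof, part, all_ocean)
  expect_equal(rs$provenance, "derived")
  # province 3 cells (lon > 16) are excluded even inside the 1-deg buffer
  expect_equal(sum(rs$br[, ocean_grid$lon > 17.5]), 0)
  expect_gt(sum(rs$br[, ocean_grid$lon < -10]), 0)
  # retained shares conserve all but the dropped provinces' mass
  expect_gte(80 / 82, 1 - 1 * 0.033 - 2 / 82)
})

test_that("benthic ranges intersect kept depth layers and provinces", {
  part <- band_partition(ocean_grid)
  # 60% west-shallow (zone 1, prov 1), 40% mid-deep (zone 2, prov 2)
  occ <- occ_tbl(
    lon = c(runif(60, -25, -10), runif(40, 6, 10)),
    lat = runif(100, -20, 20)
  )
  prof <- tibble::tibble(taxon_id = "sp", habitat_label = "demersal",
                         bottom_class = "demersal", coast_class = "generalist")
  rs <- derive_range(occ, prof, part, all_ocean)
  # pre-buffer range = (zone1 U zone2) & (prov1 U prov2) & bbox; province 3
  # never enters
  expect_equal(sum(rs$br[, ocean_grid$lon > 17.5]), 0)
  expect_gt(sum(rs$br), 0)
})

test_that("arctic units below the occurrence-share floor are dropped", {
  grid <- ocean_grid
  lon_m <- matrix(grid$lon, length(grid$lat), length(grid$lon), byrow = TRUE)
  lat_m <- matrix(grid$lat, length(grid$lat), length(grid$lon))
  prov <- matrix(1L, nrow(lat_m), ncol(lat_m))
  prov[lat_m > 20] <- 2L                      # northern band = arctic
  zones <- matrix(1L, nrow(lat_m), ncol(lat_m))
  units <- matrix(NA_integer_, nrow(lat_m), ncol(lat_m))
  units[prov == 2L] <- ifelse(lon_m[prov == 2L] < 5, 1L, 2L)
  part <- bio_partition(grid, prov, zones, units, arctic_province_id = 2L)
  # 997 records in unit 1, 3 in unit 2 (0.3% <= 0.5%), plus a southern mass
  occ <- occ_tbl(
    lon = c(runif(600, -20, 0), runif(397, -20, 0), runif(3, 10, 20)),
    lat = c(runif(600, 0, 15), runif(397, 25, 35), runif(3, 25, 35))
  )
  prof <- tibble::tibble(taxon_id = "sp", habitat_label = "pelagic",
                         bottom_class = "pelagic", coast_class = "oceanic")
  rs <- derive_range(occ, prof, part, all_ocean)
  # arctic unit 2 (lon > 5, lat > 21) is dropped from the pre-buffer range;
  # allow the 1-degree buffer at the unit boundary
  expect_equal(sum(rs$br[lat_m > 22 & lon_m > 7]), 0)
  expect_gt(sum(rs$br[lat_m > 22 & lon_m < 3]), 0)
})

test_that("the cumulative-tail province filter is available as a switch", {
  part <- band_partition(ocean_grid)
  # shares 2%, 3%, 95%: per-unit drops the 2% and 3% provinces; the
  # cumulative reading drops only the smallest (2% <= 3.3% but 2%+3% > 3.3%)
  occ <- occ_tbl(
    lon = c(runif(2, -25, -10), runif(3, -5, 10), runif(95, 20, 35)),
    lat = runif(100, -20, 20)
  )
  prof <- tibble::tibble(taxon_id = "sp", habitat_label = "pelagic",
                         bottom_class = "pelagic", coast_class = "oceanic")
  per_unit <- derive_range(occ, prof, part, all_ocean)
  cumul <- derive_range(occ, prof, part, all_ocean,
                        filter_mode = "cumulative")
  expect_equal(sum(per_unit$br[, ocean_grid$lon < -11]), 0)
  expect_gt(sum(cumul$br[, ocean_grid$lon %in%
                           ocean_grid$lon[ocean_grid$lon > -5 &
                                            ocean_grid$lon < 10]]), 0)
  expect_gt(sum(cumul$br), sum(per_unit$br))
})

test_that("re-flagging by range membership partitions every record", {
  erm <- rect_mask(ocean_grid, 0, 10, 0, 10)
  rs <- build_from_erm(erm, ocean_grid, all_ocean)
  occ <- occ_tbl(lon = c(5, 12, 35, 6), lat = c(5, 5, 35, 6),
                 flag = c(NA, 1L, NA, 0L))
  out <- reflag_by_range(occ, rs)
  expect_equal(out$flag, c(1L, 0L, 0L, 0L))  # pre-flagged 0 stays 0
  expect_true(all(out$flag %in% c(0L, 1L)))
})
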