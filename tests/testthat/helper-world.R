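# Shared small fixtures, built once per test run.

tiny_world <- make_world(extent = c(-10, 10, -15, 15), res = 0.2, seed = 42)

tiny_species <- make_species(
  tiny_world, "tsp", "pelagic",
  tibble::tibble(variable = "temperature", centre = 24, breadth = 3)
)

# an all-ocean grid for pure-geometry tests
ocean_grid <- sdm_grid(c(-30, 40, -30, 40), 0.5)
all_ocean <- matrix(TRUE, length(ocean_grid$lat), length(ocean_grid$lon))

# rectangle mask helper (cell centres inside the closed box)
rect_mask <- function(grid, lon_min, lon_max, lat_min, lat_max) {
  outer(grid$lat >= lat_min & grid$lat <= lat_max,
        grid$lon >= lon_min & grid$lon <= lon_max, "&")
}

# quick raw-occurrence constructor
occ_tbl <- function(lon, lat, taxon_id = "sp", year = 2010L, month = 6L,
                    source = "obis", flags = "", flag = NA_integer_,
                    basis = "observation") {
  tibble::tibble(
    taxon_id = taxon_id, lon = lon, lat = lat,
    year = year, month = month, basis_of_record = basis,
    source = source, original_flags = flags, flag = flag
  )
}
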