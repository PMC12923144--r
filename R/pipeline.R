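#' Pipeline configuration
#'
#' All tunable thresholds of the per-species workflow in one place. The
#' defaults are the pipeline's reference values: 90% coastal share for the
#' neritic/oceanic rule, 3.3% province (and depth-layer) retention, 0.5%
#' Arctic-unit retention, automatic 20/30 km spatial thinning, 1 and 10
#' degree range buffers, 2.5-97.5 percentile envelope, 80-1000 km
#' pseudo-absence ring, presence prevalence 0.7, TSS retention gate 0.6, and
#' the standard environmental bin sizes.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    coastal_threshold = 0.9,
    province_share = 0.033,
    arctic_share = 0.005,
    thin_distance_km = NULL,      # NULL = automatic 0/20/30 km rule
    buffer_br = 1,
    buffer_pr = 10,
    envelope_probs = c(0.025, 0.975),
    disk_min_km = 80,
    disk_max_km = 1000,
    prevalence = 0.7,
    tss_gate = 0.6,
    bins = default_binning_scheme(),
    n_folds = 5,
    repeats = 3,
    unique_env_cutoff = 1000,
    pseudo_occurrence_max = 1000,
    algorithms = names(algorithm_registry()),
    scenarios = list(c(period = "2050s", scenario = "ssp585")),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Report config deviations from the defaults
#'
#' @param config A [pipeline_config()].
#' @return Tibble of keys whose value differs from the default.
#' @export
config_diff <- function(config) {
  ref <- pipeline_config()
  keys <- names(ref)[!vapply(names(ref), function(k) {
    isTRUE(all.equal(config[[k]], ref[[k]]))
  }, logical(1))]
  tibble::tibble(
    key = keys,
    value = vapply(keys, function(k) paste(format(config[[k]]),
                                           collapse = ","), character(1)),
    default = vapply(keys, function(k) paste(format(ref[[k]]),
                                             collapse = ","), character(1))
  )
}

stage_fail <- function(stage, e) {
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_fail(stage, e))
}

#' Run the full per-species workflow
#'
#' Sequences cleaning, habitat classification, range construction,
#' environmental thinning, pseudo-absence generation, ensemble fitting,
#' projection and change indices for one species, returning every
#' intermediate plus a manifest of counts and metrics.
#'
#' @param occurrences Raw occurrence tibble.
#' @param habitat_label Habitat vocabulary label for the species.
#' @param world A [make_world()] result (or an equivalently shaped list
#'   with `grid`, `ocean`, `bathymetry`, `partition`, `surface`, `benthic`).
#' @param depth_min,depth_max Trait depth range (m) or `NA`.
#' @param erm Optional logical expert-range mask; when absent the range is
#'   derived from occurrences and the partition.
#' @param future_stacks Optional named list of future [env_stack()]s to
#'   project onto (defaults to [future_stack()] per configured scenario).
#' @param config A [pipeline_config()].
#' @return A list with elements `occurrences` (final flagged table),
#'   `profile`, `range`, `training`, `folds`, `runs`, `ensemble`,
#'   `projection_present`, `projections_future`, `change`, and `manifest`
#'   (stage ledger tibble with counts and the verified/erroneous/unflagged
#'   shares).
#' @export
run_species <- function(occurrences, habitat_label, world,
                        depth_min = NA, depth_max = NA, erm = NULL,
                        future_stacks = NULL, config = pipeline_config()) {
  grid <- world$grid
  manifest <- list()
  note <- function(stage, n, detail = "") {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, n = n, detail = detail
    )
  }

  # 1. clean ----------------------------------------------------------------
  occ <- run_stage("clean", {
    occurrences |>
      standardize_flags() |>
      clean_coordinates() |>
      deduplicate()
  })
  note("clean", nrow(occ))

  # 2. habitat classification ----------------------------------------------
  coastal <- !is.na(world$partition$depth_zones) &
    world$partition$depth_zones == 1L
  profile <- run_stage("d3os", species_profile(
    taxon_id = occ$taxon_id[1], habitat_label = habitat_label,
    depth_min = depth_min, depth_max = depth_max,
    records = occ, coastal_mask = coastal,
    bathymetry = world$bathymetry, grid = grid
  ))
  note("d3os", 1, paste(profile$bottom_class, profile$coast_class, sep = "/"))

  # 3. range ----------------------------------------------------------------
  rng <- run_stage("range", {
    if (!is.null(erm)) {
      build_from_erm(erm, grid, world$ocean,
                     buffer_br = config$buffer_br,
                     buffer_pr = config$buffer_pr,
                     taxon_id = profile$taxon_id)
    } else {
      thinned <- spatial_thin(occ, seed = config$seed,
                              distance_km = config$thin_distance_km)
      derive_range(thinned, profile, world$partition, world$ocean,
                   province_share = config$province_share,
                   arctic_share = config$arctic_share,
                   buffer_br = config$buffer_br,
                   buffer_pr = config$buffer_pr)
    }
  })
  occ <- run_stage("range", reflag_by_range(occ, rng))
  note("range", sum(rng$br), rng$provenance)

  stratum <- if (profile$bottom_class == "pelagic") "surface" else "benthic"
  stack <- world[[stratum]]

  # 4. training presences: pseudo-occurrences + environmental thinning ------
  valid <- occ[!is.na(occ$flag) & occ$flag == 1L, , drop = FALSE]
  if (!is.null(erm) && nrow(valid) < config$pseudo_occurrence_max) {
    pocc <- run_stage("env_thin", generate_pseudo_occurrences(
      erm, world$bathymetry, grid, depth_min, depth_max,
      seed = config$seed, exclude = valid, taxon_id = profile$taxon_id
    ))
    valid <- dplyr::bind_rows(valid, pocc)
  }
  keys <- run_stage("env_thin", bin_environment(stack, config$bins))
  presences <- run_stage("env_thin",
                         env_thin(valid, keys, grid, seed = config$seed))
  note("env_thin", nrow(presences))

  # 5. pseudo-absences -------------------------------------------------------
  pres_env <- env_at(stack, presences$lon, presences$lat)
  vars <- names(stack$layers)
  n_pa <- nrow(presences)
  pas <- run_stage("pseudo_absence", {
    if (profile$bottom_class == "pelagic") {
      env_ok <- pres_env[stats::complete.cases(pres_env[vars]), vars]
      envl <- fit_envelope(env_ok, probs = config$envelope_probs)
      sample_pa_sre(stack, envl, rng$pr, n_pa, seed = config$seed)
    } else {
      sample_pa_disk(presences, rng$pr, world$ocean, grid, n_pa,
                     min_km = config$disk_min_km,
                     max_km = config$disk_max_km, seed = config$seed)
    }
  })
  note("pseudo_absence", nrow(pas))

  # 6. ensemble --------------------------------------------------------------
  pa_env <- env_at(stack, pas$lon, pas$lat)
  training <- run_stage("ensemble", make_training(
    pres_env[stats::complete.cases(pres_env[vars]), vars],
    pa_env[stats::complete.cases(pa_env[vars]), vars],
    prevalence = config$prevalence
  ))
  # after environmental thinning, one presence remains per occupied unique
  # environment, so the presence count is the species' unique-environment count
  n_unique <- nrow(presences)
  folds <- run_stage("ensemble", make_folds(
    training, n_unique_env = n_unique, n_folds = config$n_folds,
    repeats = config$repeats, unique_env_cutoff = config$unique_env_cutoff,
    seed = config$seed
  ))
  runs <- run_stage("ensemble", fit_sdm_runs(training, folds,
                                             algorithms = config$algorithms))
  ensemble <- run_stage("ensemble",
                        build_ensemble(runs, training,
                                       tss_gate = config$tss_gate))
  note("ensemble", length(ensemble$retained),
       sprintf("%d runs total", nrow(runs)))

  # 7. projection ------------------------------------------------------------
  proj_now <- run_stage("project", project_ensemble(ensemble, stack, rng$pr))
  if (is.null(future_stacks)) {
    future_stacks <- lapply(config$scenarios, function(sc) {
      future_stack(world, period = sc[["period"]],
                   scenario = sc[["scenario"]], stratum = stratum)
    })
    names(future_stacks) <- vapply(config$scenarios, function(sc) {
      paste(sc[["period"]], sc[["scenario"]], sep = "_")
    }, character(1))
  }
  proj_fut <- lapply(future_stacks, function(fs) {
    run_stage("project", project_ensemble(ensemble, fs, rng$pr))
  })
  note("project", 1 + length(proj_fut))

  # 8. change ----------------------------------------------------------------
  thr <- ensemble_threshold(ensemble)
  bin_now <- binarize(proj_now$hsi, thr)
  change <- lapply(proj_fut, function(p) {
    run_stage("change",
              change_indices(bin_now, binarize(p$hsi, thr), rng$pr, grid))
  })
  note("change", length(change))

  ledger <- tibble::tibble(
    verified = mean(occ$flag == 1L, na.rm = TRUE),
    erroneous = mean(occ$flag == 0L, na.rm = TRUE),
    unflagged = mean(is.na(occ$flag))
  )
  list(
    occurrences = occ, profile = profile, range = rng,
    presences = presences, pseudo_absences = pas,
    training = training, folds = folds, runs = runs, ensemble = ensemble,
    projection_present = proj_now, projections_future = proj_fut,
    change = change, threshold = thr,
    manifest = dplyr::bind_rows(manifest), flag_ledger = ledger,
    config = config
  )
}
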