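toy_training <- function(n1 = 80, n0 = 80, seed = 1, sep = 8) {
  # separable-by-temperature toy problem with a second nuisance variable
  set.seed(seed)
  make_training(
    data.frame(temperature = rnorm(n1, 20 + sep / 2, 1),
               salinity = rnorm(n1, 35, 0.5)),
    data.frame(temperature = rnorm(n0, 20 - sep / 2, 1),
               salinity = rnorm(n0, 35, 0.5))
  )
}

test_that("training weights give the presence class its prevalence share", {
  tr <- toy_training(n1 = 30, n0 = 90)
  w1 <- sum(tr$weight[tr$label == 1])
  expect_equal(w1 / sum(tr$weight), 0.7)
  expect_equal(sum(tr$weight), nrow(tr))
  tr2 <- make_training(data.frame(a = 1:5), data.frame(a = 6:10),
                       prevalence = 0.5)
  expect_equal(sum(tr2$weight[tr2$label == 1]) / sum(tr2$weight), 0.5)
  expect_error(make_training(data.frame(a = 1:2), data.frame(b = 1:2)),
               "share columns")
})

test_that("fold plan size follows the unique-environment rule", {
  set.seed(2)
  vars <- c("dissolved_oxygen", "temperature", "ph", "primary_productivity",
            "salinity", "water_velocity")
  pres <- as.data.frame(setNames(lapply(vars, function(v) rnorm(60)), vars))
  abs <- as.data.frame(setNames(lapply(vars, function(v) rnorm(60, 2)), vars))
  tr <- make_training(pres, abs)
  env_plan <- make_folds(tr, n_unique_env = 1500)
  expect_equal(nrow(env_plan), 30)             # 6 variables x 5 folds
  expect_setequal(unique(env_plan$scheme), vars)
  rand_plan <- make_folds(tr, n_unique_env = 400, seed = 3)
  expect_equal(nrow(rand_plan), 15)            # 5 folds x 3 repeats
  # every held-out fold contains both classes
  for (ix in c(env_plan$test, rand_plan$test)) {
    expect_setequal(unique(tr$label[ix]), c(0L, 1L))
  }
  # folds within a scheme partition the rows
  for (sc in vars) {
    rows <- sort(unlist(env_plan$test[env_plan$scheme == sc]))
    expect_equal(rows, seq_len(nrow(tr)))
  }
})

test_that("confusion metrics match hand evaluation of the formulas", {
  m <- confusion_metrics(tp = 40, fp = 5, fn = 10, tn = 45)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$tss, 0.7)
  expect_equal(m$csi, 40 / 55)
})

test_that("threshold search and AUC behave on canonical cases", {
  # perfect ranking
  m <- evaluate_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$tss, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$csi, 1)
  expect_gt(m$threshold, 0.2)
  # AUC agrees with an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(4)
  truth <- rep(c(0, 1), each = 50)
  pred <- runif(100) + 0.3 * truth
  ours <- evaluate_predictions(pred, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, pred, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_error(evaluate_predictions(runif(5), rep(1, 5)), "both classes")
})

test_that("every algorithm fits the toy problem and respects the codomain", {
  tr <- toy_training()
  plan <- make_folds(tr, n_unique_env = 100, repeats = 1, seed = 1)
  test_ix <- plan$test[[1]]
  train <- tr[-test_ix, ]; test <- tr[test_ix, ]
  for (a in names(algorithm_registry())) {
    run <- fit_predict_run(a, train, test)
    expect_false(run$failed)
    expect_gte(run$tss, 0.8)      # cleanly separable problem
    pred <- run$model[[1]]$predict(test[, c("temperature", "salinity")])
    expect_true(all(pred >= 0 & pred <= 1), info = a)
  }
})

test_that("shuffled labels give chance-level AUC and failures are contained", {
  tr <- toy_training(seed = 6)
  set.seed(7)
  tr$label <- sample(tr$label)
  attr(tr, "variables") <- c("temperature", "salinity")
  plan <- make_folds(tr, n_unique_env = 100, repeats = 1, seed = 2)
  run <- fit_predict_run("glm", tr[-plan$test[[1]], ], tr[plan$test[[1]], ])
  expect_lt(abs(run$auc - 0.5), 0.35)   # single-fold Monte-Carlo slack
  # a tuning hook that errors marks the run failed instead of raising
  boom <- function(...) stop("no luck")
  bad <- fit_predict_run("glm", tr[-plan$test[[1]], ], tr[plan$test[[1]], ],
                         tuning_hook = boom)
  expect_true(bad$failed)
  expect_match(bad$message, "no luck")
})

stub_runs <- function(tss, preds, thresholds = NULL) {
  thresholds <- thresholds %||% rep(0.5, length(tss))
  tibble::tibble(
    scheme = "s", fold = seq_along(tss), algorithm = "stub",
    tss = tss, auc = 0.9, csi = 0.8, threshold = thresholds,
    sensitivity = 0.9, specificity = 0.9, failed = FALSE,
    message = NA_character_,
    model = lapply(preds, function(p) {
      force(p)
      list(predict = function(newX) rep(p, nrow(newX)))
    })
  )
}

stub_training <- function() {
  tr <- tibble::tibble(temperature = c(1, 2, 3), label = c(1L, 0L, 1L),
                       weight = 1)
  attr(tr, "variables") <- "temperature"
  tr
}

test_that("the TSS gate retains exactly the runs above 0.6", {
  runs <- stub_runs(c(0.55, 0.65, 0.70), preds = c(0.2, 0.8, 0.9))
  ens <- build_ensemble(runs, stub_training())
  expect_equal(ens$retained, c(2L, 3L))
  expect_error(build_ensemble(stub_runs(c(0.1, 0.2), c(0.5, 0.5)),
                              stub_training()),
               "best TSS 0.200")
})

test_that("committee averaging is the vote fraction at per-run thresholds", {
  runs <- stub_runs(c(0.9, 0.9, 0.9), preds = c(0.8, 0.7, 0.2),
                    thresholds = c(0.5, 0.5, 0.5))
  ens <- build_ensemble(runs, stub_training())
  newX <- data.frame(temperature = c(10, 20))
  out <- predict(ens, newX)
  expect_equal(out$committee, c(2 / 3, 2 / 3))   # votes {1,1,0}
  expect_equal(out$mean, rep(mean(c(0.8, 0.7, 0.2)), 2))
  # identical predictions across runs: zero dispersion
  same <- build_ensemble(stub_runs(c(0.9, 0.9), preds = c(0.6, 0.6)),
                         stub_training())
  expect_equal(predict(same, newX)$cv, c(0, 0))
  expect_equal(predict(same, newX)$committee, c(1, 1))
})

test_that("ensemble outputs are invariant to run order and duplication", {
  runs <- stub_runs(c(0.7, 0.8, 0.9), preds = c(0.3, 0.6, 0.9))
  newX <- data.frame(temperature = 1:3)
  base <- predict(build_ensemble(runs, stub_training()), newX)
  perm <- predict(build_ensemble(runs[c(3, 1, 2), ], stub_training()), newX)
  expect_equal(base, perm)
  # duplicating a retained run shifts the mean toward it but committee
  # semantics stay consistent: all-presence iff every run votes presence
  hi <- build_ensemble(stub_runs(c(0.8, 0.8), preds = c(0.9, 0.9)),
                       stub_training())
  expect_equal(predict(hi, newX)$committee, rep(1, 3))
  lo <- build_ensemble(stub_runs(c(0.8, 0.8), preds = c(0.1, 0.1)),
                       stub_training())
  expect_equal(predict(lo, newX)$committee, rep(0, 3))
})

test_that("tidy and glance summarise the run ledger", {
  runs <- stub_runs(c(0.55, 0.65), preds = c(0.4, 0.8))
  ens <- build_ensemble(runs, stub_training())
  td <- tidy(ens)
  expect_equal(td$retained, c(FALSE, TRUE))
  gl <- glance(ens)
  expect_equal(gl$n_runs, 2L)
  expect_equal(gl$n_retained, 1L)
  expect_equal(gl$mean_tss, 0.65)
})
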