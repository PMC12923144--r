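#' Assemble a weighted presence / pseudo-absence training set
#'
#' Binds presence and pseudo-absence environment rows into one modelling
#' table and assigns case weights so the presence class carries `prevalence`
#' of the total weight (default 0.7) and the pseudo-absence class the rest,
#' normalised to sum to the number of rows.
#'
#' @param presence_env Tibble of environment values at presence cells.
#' @param absence_env Tibble of environment values at pseudo-absence cells
#'   (same columns).
#' @param prevalence Presence-class weight share, default 0.7.
#' @return Tibble with the environment columns plus `label` (1 presence,
#'   0 pseudo-absence) and `weight`.
#' @export
make_training <- function(presence_env, absence_env, prevalence = 0.7) {
  stopifnot(prevalence > 0, prevalence < 1)
  presence_env <- tibble::as_tibble(presence_env)
  absence_env <- tibble::as_tibble(absence_env)
  vars <- names(presence_env)
  if (!setequal(vars, names(absence_env))) {
    stop("presence and absence tables must share columns", call. = FALSE)
  }
  n1 <- nrow(presence_env); n0 <- nrow(absence_env)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty", call. = FALSE)
  out <- dplyr::bind_rows(
    dplyr::mutate(presence_env, label = 1L),
    dplyr::mutate(absence_env[, vars], label = 0L)
  )
  w <- ifelse(out$label == 1L, prevalence / n1, (1 - prevalence) / n0)
  out$weight <- w / sum(w) * nrow(out)
  if (anyNA(out[vars])) stop("training set contains missing environment values",
                             call. = FALSE)
  attr(out, "variables") <- vars
  attr(out, "prevalence") <- prevalence
  out
}

training_vars <- function(training) {
  attr(training, "variables") %||%
    setdiff(names(training), c("label", "weight"))
}

#' Plan cross-validation folds
#'
#' With more than `unique_env_cutoff` unique environments, folds are blocked
#' in environmental space: for every modelling variable, five quantile blocks
#' along that variable (built separately inside the presence and the
#' pseudo-absence class so folds stay balanced) make one 5-fold scheme,
#' giving `variables x 5` held-out assignments per algorithm. Otherwise the
#' plan is random stratified 5-fold cross-validation repeated 3 times (15
#' assignments per algorithm).
#'
#' @param training Training tibble from [make_training()].
#' @param n_unique_env Number of unique binned environments in the modelled
#'   region.
#' @param n_folds Folds per scheme, default 5.
#' @param repeats Repeats for the random path, default 3.
#' @param unique_env_cutoff Switch point, default 1000.
#' @param seed Seed for the random path.
#' @return Tibble with columns `scheme`, `fold`, `test` (list of held-out row
#'   indices); one row per modelling run per algorithm.
#' @export
make_folds <- function(training, n_unique_env, n_folds = 5, repeats = 3,
                       unique_env_cutoff = 1000, seed = 1L) {
  if (nrow(training) == 0) stop("empty training set", call. = FALSE)
  if (!all(c(0L, 1L) %in% training$label)) {
    stop("training set must contain both classes", call. = FALSE)
  }
  vars <- training_vars(training)
  n <- nrow(training)
  if (n_unique_env > unique_env_cutoff) {
    plan <- purrr::map_dfr(vars, function(v) {
      fold_id <- integer(n)
      for (cls in c(0L, 1L)) {
        rows <- which(training$label == cls)
        rk <- rank(training[[v]][rows], ties.method = "first")
        fold_id[rows] <- as.integer(ceiling(rk / length(rows) * n_folds))
      }
      tibble::tibble(
        scheme = v, fold = seq_len(n_folds),
        test = lapply(seq_len(n_folds), function(k) which(fold_id == k))
      )
    })
  } else {
    plan <- with_seed(seed, purrr::map_dfr(seq_len(repeats), function(r) {
      fold_id <- integer(n)
      for (cls in c(0L, 1L)) {
        rows <- which(training$label == cls)
        fold_id[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
      }
      tibble::tibble(
        scheme = paste0("rep", r), fold = seq_len(n_folds),
        test = lapply(seq_len(n_folds), function(k) which(fold_id == k))
      )
    }))
  }
  # every held-out fold must contain both classes
  bad <- vapply(plan$test, function(ix) {
    length(unique(training$label[ix])) < 2
  }, logical(1))
  if (any(bad)) {
    stop("fold(s) lacking both classes; training set too small or ",
         "degenerate for this fold plan", call. = FALSE)
  }
  plan
}

#' Classification metrics from a confusion table
#'
#' True skill statistic (sensitivity + specificity - 1) and critical success
#' index (`TP / (TP + FP + FN)`).
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Tibble with `sensitivity`, `specificity`, `tss`, `csi`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    tss = sens + spec - 1,
    csi = tp / (tp + fp + fn)
  )
}

#' Evaluate suitability predictions against labels
#'
#' Sweeps candidate thresholds (the unique predicted values) and keeps the
#' one maximising the true skill statistic; reports TSS, CSI and sensitivity
#' / specificity at that threshold plus the threshold-free AUC (Mann-Whitney
#' rank statistic). Presence is predicted where `predicted >= threshold`.
#'
#' @param predicted Numeric suitability vector in `[0, 1]`.
#' @param truth Integer labels (1 presence, 0 absence).
#' @return A list: `tss`, `auc`, `csi`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  stopifnot(length(predicted) == length(truth))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  ths <- sort(unique(predicted))
  stats_at <- vapply(ths, function(t) {
    pos <- predicted >= t
    c(tp = sum(pos & truth == 1L), fp = sum(pos & truth == 0L))
  }, numeric(2))
  sens <- stats_at["tp", ] / n1
  spec <- (n0 - stats_at["fp", ]) / n0
  tss <- sens + spec - 1
  best <- which.max(tss)
  tp <- unname(stats_at["tp", best]); fp <- unname(stats_at["fp", best])
  fn <- n1 - tp
  r <- rank(predicted)
  auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(
    tss = tss[best], auc = auc, csi = tp / (tp + fp + fn),
    threshold = min(max(ths[best], 1e-6), 1 - 1e-6),
    sensitivity = sens[best], specificity = spec[best]
  )
}

scale_train <- function(X) {
  mu <- vapply(X, mean, numeric(1))
  sd <- vapply(X, stats::sd, numeric(1))
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd,
       apply = function(newX) {
         sweep(sweep(as.matrix(newX), 2, mu), 2, sd, "/")
       })
}

quad_expand <- function(X) {
  X <- as.matrix(X)
  cbind(X, X^2)
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

#' Ensemble algorithm registry
#'
#' The ten algorithm families of the ensemble, each a fitter returning a
#' suitability predictor. Where a family's canonical implementation is not a
#' package dependency, an in-family equivalent is used: `fda` is a
#' regularised discriminant on quadratic features (`MASS::lda`), `gbm` a
#' slow-learning depth-3 gradient-boosted tree (`xgboost`), `maxnet` a
#' lasso-penalised logistic regression on quadratic features (`glmnet`,
#' which is also the computational core of maximum-entropy fitting) and
#' `mars` a natural-spline logistic regression (`splines::ns`).
#'
#' @return Named list of fitting functions `f(X, y, w)` returning a list
#'   with elements `fit` and `predict` (maps new environment rows to
#'   suitabilities in `[0, 1]`).
#' @export
algorithm_registry <- function() {
  list(
    glm = function(X, y, w) {
      d <- data.frame(X, .y = y)
      f <- stats::as.formula(paste(
        ".y ~", paste(sprintf("%s + I(%s^2)", names(X), names(X)),
                      collapse = " + ")
      ))
      fit <- suppressWarnings(
        stats::glm(f, data = d, family = stats::binomial(), weights = w)
      )
      list(fit = fit, predict = function(newX) {
        clamp01(suppressWarnings(
          stats::predict(fit, newdata = as.data.frame(newX),
                         type = "response")
        ))
      })
    },
    gam = function(X, y, w) {
      k <- max(3, min(6, floor(nrow(X) / 10)))
      d <- data.frame(X, .y = y)
      f <- stats::as.formula(paste(
        ".y ~", paste(sprintf("s(%s, k = %d)", names(X), k), collapse = " + ")
      ))
      fit <- suppressWarnings(
        mgcv::gam(f, data = d, family = stats::binomial(), weights = w,
                  method = "REML")
      )
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, newdata = as.data.frame(newX),
                               type = "response"))
      })
    },
    rf = function(X, y, w) {
      prev <- sum(w[y == 1]) / sum(w)
      fit <- randomForest::randomForest(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
        ntree = 300, classwt = c("0" = 1 - prev, "1" = prev)
      )
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, newdata = as.data.frame(newX),
                               type = "prob")[, "1"])
      })
    },
    ann = function(X, y, w) {
      sc <- scale_train(X)
      fit <- nnet::nnet(sc$apply(X), y, size = 5, decay = 0.05,
                        maxit = 300, weights = w, trace = FALSE)
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, sc$apply(newX)))
      })
    },
    fda = function(X, y, w) {
      Z <- quad_expand(X)
      prev <- sum(w[y == 1]) / sum(w)
      fit <- MASS::lda(Z, grouping = factor(y, levels = c(0, 1)),
                       prior = c(1 - prev, prev))
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, quad_expand(newX))$posterior[, "1"])
      })
    },
    cta = function(X, y, w) {
      d <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                          control = rpart::rpart.control(cp = 0.005,
                                                         minbucket = 5))
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, newdata = as.data.frame(newX),
                               type = "prob")[, "1"])
      })
    },
    gbm = function(X, y, w) {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.05, subsample = 0.8),
        data = xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w),
        nrounds = 150
      )
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, as.matrix(newX)))
      })
    },
    maxnet = function(X, y, w) {
      Z <- quad_expand(X)
      lam <- tryCatch(
        glmnet::cv.glmnet(Z, y, family = "binomial", weights = w,
                          alpha = 1, nfolds = 3)$lambda.min,
        error = function(e) 0.01
      )
      fit <- glmnet::glmnet(Z, y, family = "binomial", weights = w,
                            alpha = 1, lambda = lam)
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, quad_expand(newX), type = "response")[, 1])
      })
    },
    xgboost = function(X, y, w) {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6,
                      eta = 0.3),
        data = xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w),
        nrounds = 60
      )
      list(fit = fit, predict = function(newX) {
        clamp01(stats::predict(fit, as.matrix(newX)))
      })
    },
    mars = function(X, y, w) {
      d <- data.frame(X, .y = y)
      f <- stats::as.formula(paste(
        ".y ~", paste(sprintf("splines::ns(%s, df = 3)", names(X)),
                      collapse = " + ")
      ))
      fit <- suppressWarnings(
        stats::glm(f, data = d, family = stats::binomial(), weights = w)
      )
      list(fit = fit, predict = function(newX) {
        clamp01(suppressWarnings(
          stats::predict(fit, newdata = as.data.frame(newX),
                         type = "response")
        ))
      })
    }
  )
}

#' Fit and evaluate one modelling run
#'
#' Fits one algorithm on the training rows and evaluates it on the held-out
#' rows. A fitting failure does not raise: the run comes back flagged
#' `failed` and is excluded downstream.
#'
#' @param algorithm_id One of the ids in [algorithm_registry()].
#' @param train,test Row tibbles with environment columns plus `label` and
#'   `weight` (both classes present in `train`).
#' @param variables Environment column names.
#' @param tuning_hook Optional callback `f(algorithm_id, X, y, w)` returning
#'   a fitted `list(fit, predict)` to replace the default settings.
#' @return A one-row tibble: `algorithm`, metrics, `threshold`, `failed`,
#'   and the fitted predictor in the `model` list-column.
#' @export
fit_predict_run <- function(algorithm_id, train, test, variables = NULL,
                            tuning_hook = NULL) {
  variables <- variables %||% training_vars(train)
  reg <- algorithm_registry()
  if (!algorithm_id %in% names(reg)) {
    stop("unknown algorithm id: ", algorithm_id, call. = FALSE)
  }
  X <- as.data.frame(train[, variables])
  y <- train$label
  w <- train$weight %||% rep(1, nrow(train))
  fitted <- tryCatch({
    if (!is.null(tuning_hook)) {
      tuning_hook(algorithm_id, X, y, w) %||% reg[[algorithm_id]](X, y, w)
    } else {
      reg[[algorithm_id]](X, y, w)
    }
  }, error = function(e) e)
  if (inherits(fitted, "error")) {
    return(tibble::tibble(
      algorithm = algorithm_id, tss = NA_real_, auc = NA_real_,
      csi = NA_real_, threshold = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, failed = TRUE,
      message = conditionMessage(fitted), model = list(NULL)
    ))
  }
  pred <- fitted$predict(as.data.frame(test[, variables]))
  m <- evaluate_predictions(pred, test$label)
  tibble::tibble(
    algorithm = algorithm_id, tss = m$tss, auc = m$auc, csi = m$csi,
    threshold = m$threshold, sensitivity = m$sensitivity,
    specificity = m$specificity, failed = FALSE, message = NA_character_,
    model = list(fitted)
  )
}

#' Fit the full run ledger (algorithms x fold plan)
#'
#' @param training Training tibble from [make_training()].
#' @param folds Fold plan from [make_folds()].
#' @param algorithms Algorithm ids, default all ten.
#' @param tuning_hook Optional hyperparameter hook (see
#'   [fit_predict_run()]).
#' @return Run tibble: one row per algorithm per fold assignment, with
#'   `scheme`, `fold`, metrics, `threshold` and the fitted predictor.
#' @export
fit_sdm_runs <- function(training, folds,
                         algorithms = names(algorithm_registry()),
                         tuning_hook = NULL) {
  vars <- training_vars(training)
  purrr::map_dfr(seq_len(nrow(folds)), function(i) {
    test_ix <- folds$test[[i]]
    train <- training[-test_ix, , drop = FALSE]
    test <- training[test_ix, , drop = FALSE]
    purrr::map_dfr(algorithms, function(a) {
      run <- fit_predict_run(a, train, test, variables = vars,
                             tuning_hook = tuning_hook)
      run$scheme <- folds$scheme[i]
      run$fold <- folds$fold[i]
      run
    })
  }) |>
    dplyr::relocate("scheme", "fold")
}

#' Gate runs and build the ensemble
#'
#' Keeps runs whose held-out TSS strictly exceeds the gate (default 0.6) and
#' packages them with per-variable calibration ranges from the training set.
#' Ensemble outputs are the unweighted mean suitability, the committee
#' average (fraction of retained runs voting presence at their own
#' TSS-maximising threshold) and the per-cell coefficient of variation.
#'
#' @param runs Run tibble from [fit_sdm_runs()].
#' @param training Training tibble (for calibration ranges).
#' @param tss_gate Retention gate on TSS (strict `>`), default 0.6.
#' @return An `sdm_ensemble` object.
#' @export
build_ensemble <- function(runs, training, tss_gate = 0.6) {
  ok <- !runs$failed & !is.na(runs$tss) & runs$tss > tss_gate
  if (!any(ok)) {
    stop(sprintf(
      "no run passed the TSS gate of %.2f (best TSS %.3f)",
      tss_gate, max(runs$tss, na.rm = TRUE)
    ), call. = FALSE)
  }
  vars <- training_vars(training)
  calib <- purrr::map_dfr(vars, function(v) {
    tibble::tibble(variable = v, min = min(training[[v]]),
                   max = max(training[[v]]))
  })
  structure(
    list(
      runs = runs, retained = which(ok), tss_gate = tss_gate,
      variables = vars, calibration_ranges = calib,
      prevalence = attr(training, "prevalence") %||% NA_real_
    ),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sdm_ensemble> %d/%d runs retained (TSS > %.2f), %d variables\n",
    length(x$retained), nrow(x$runs), x$tss_gate, length(x$variables)
  ))
  invisible(x)
}

#' Predict ensemble suitability for new environments
#'
#' @param object An [build_ensemble()] result.
#' @param newdata Tibble/data frame of environment rows (the ensemble's
#'   variables as columns).
#' @param ... Unused.
#' @return Tibble with `mean` (unweighted mean suitability), `committee`
#'   (vote fraction) and `cv` (coefficient of variation; 0 where the mean
#'   is 0) per row.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$variables, drop = FALSE]
  kept <- object$runs[object$retained, ]
  P <- vapply(seq_len(nrow(kept)), function(i) {
    kept$model[[i]]$predict(newdata)
  }, numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  votes <- sweep(P, 2, kept$threshold, ">=")
  mu <- rowMeans(P)
  sdv <- apply(P, 1, stats::sd)
  if (nrow(kept) == 1) sdv <- rep(0, nrow(newdata))
  tibble::tibble(
    mean = mu,
    committee = rowMeans(votes),
    cv = ifelse(mu > 0, sdv / mu, 0)
  )
}
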