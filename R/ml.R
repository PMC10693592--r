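#' Enumerate the model-algorithm combinations
#'
#' Two algorithms (random forest; elastic-net regularized GLM), two data
#' levels (box medians; individual plants), and three task-feature settings:
#' classification on presence/absence, regression on presence/absence, and
#' regression on strain colonization. Classification uses presence features
#' only, so the enumeration yields exactly 12 combinations (4 classification
#' + 8 regression).
#'
#' @return Tibble with `config_id`, `algorithm`, `task`, `features`, `level`.
#' @export
enumerate_configs <- function() {
  grid <- expand.grid(
    algorithm = c("RF", "GLMNet"),
    level = c("median", "individual"),
    setting = c("classification_presence", "regression_presence",
                "regression_colonization"),
    stringsAsFactors = FALSE)
  grid$task <- ifelse(grepl("classification", grid$setting),
                      "classification", "regression")
  grid$features <- ifelse(grepl("presence", grid$setting), "presence",
                          "colonization")
  grid <- grid[order(grid$task, grid$algorithm, grid$level, grid$features), ]
  tibble::tibble(config_id = sprintf("cfg%02d", seq_len(nrow(grid))),
                 algorithm = grid$algorithm, task = grid$task,
                 features = grid$features, level = grid$level)
}

#' Build the strain feature matrix for one analysis
#'
#' Presence features are 1 for inoculated community members; colonization
#' features are end-point log10 strain abundances (absent strains at 0). At
#' the `median` level rows are communities (box medians); at the
#' `individual` level rows are plants. The response is either the protection
#' class derived from the per-experiment density-minimum thresholds or the
#' normalized pathogen reduction; `group` ties every row to its community so
#' cross-validation can split by community.
#'
#' @param dataset A `screen_data`, log10 scale, ambiguity partitioned,
#'   normalized (`pathogen_norm` present) for regression tasks.
#' @param task `"classification"` or `"regression"`.
#' @param features `"presence"` or `"colonization"`.
#' @param level `"median"` or `"individual"`.
#' @param thresholds Tibble `experiment`, `threshold` (classification only).
#' @return A `feature_matrix`: list with `x` (matrix, one column per pool
#'   strain), `response`, `group`, `value` (log10 pathogen per row),
#'   `experiment`, and the config fields.
#' @export
build_features <- function(dataset, task = c("classification", "regression"),
                           features = c("presence", "colonization"),
                           level = c("median", "individual"),
                           thresholds = NULL) {
  stopifnot(inherits(dataset, "screen_data"), dataset$scale == "log10")
  task <- match.arg(task); features <- match.arg(features)
  level <- match.arg(level)
  if (task == "classification" && features != "presence") {
    stop("classification uses presence/absence features", call. = FALSE)
  }
  pool_ids <- sort(unique(dataset$communities$strain_id))
  pl <- dataset$plants
  pl <- pl[!(pl$treatment %in% dataset$controls) & !pl$excluded &
             !is.na(pl$pathogen_cfu) & !is.na(pl$community_id), ]
  if (task == "regression" && !("pathogen_norm" %in% names(pl))) {
    stop("regression needs normalized pathogen reduction; run normalize_pathogen",
         call. = FALSE)
  }
  memb <- split(dataset$communities$strain_id, dataset$communities$community_id)

  if (level == "median") {
    agg <- aggregate_by_box(dataset)
    agg <- agg[agg$box_id %in% pl$box_id, ]
    rows <- agg
    value <- rows$median_pathogen
    response_num <- rows$median_pathogen_norm
  } else {
    rows <- pl
    value <- rows$pathogen_cfu
    response_num <- if ("pathogen_norm" %in% names(pl)) rows$pathogen_norm else NULL
  }

  x <- matrix(0, nrow(rows), length(pool_ids),
              dimnames = list(NULL, pool_ids))
  if (features == "presence") {
    for (i in seq_len(nrow(rows))) {
      x[i, memb[[rows$community_id[i]]]] <- 1
    }
  } else {
    st <- dataset$strains
    if (level == "median") {
      st <- dplyr::left_join(st, dataset$plants[, c("plant_id", "box_id")],
                             by = "plant_id")
      med <- dplyr::summarise(dplyr::group_by(st, .data$box_id, .data$strain_id),
                              v = stats::median(.data$cfu_per_g), .groups = "drop")
      for (i in seq_len(nrow(rows))) {
        sub <- med[med$box_id == rows$box_id[i], ]
        x[i, sub$strain_id] <- sub$v
      }
    } else {
      st <- st[st$plant_id %in% rows$plant_id, ]
      for (i in seq_len(nrow(rows))) {
        sub <- st[st$plant_id == rows$plant_id[i], ]
        x[i, sub$strain_id] <- sub$cfu_per_g
      }
    }
  }

  response <- if (task == "classification") {
    if (is.null(thresholds)) stop("classification needs thresholds", call. = FALSE)
    thr <- setNames(thresholds$threshold, thresholds$experiment)
    if (any(is.na(thr[rows$experiment]))) {
      stop("missing threshold for an experiment", call. = FALSE)
    }
    factor(ifelse(value < thr[rows$experiment], "protected", "non_protected"),
           levels = c("non_protected", "protected"))
  } else {
    response_num
  }

  structure(list(x = x, response = response, group = rows$community_id,
                 value = value, experiment = rows$experiment,
                 task = task, features = features, level = level),
            class = "feature_matrix")
}

#' Community-grouped fold assignment for repeated cross-validation
#'
#' Every community (group) lands in exactly one fold per round, so no fold
#' ever contains rows of a community present in another fold of the same
#' round — the leakage guard for plant-level rows.
#'
#' @param groups Character vector, one group id per row.
#' @param n_folds Folds per round.
#' @param repeats Rounds.
#' @param seed Integer seed.
#' @return List of `repeats` named integer vectors (group -> fold).
#' @export
make_grouped_folds <- function(groups, n_folds = 5, repeats = 10, seed = 1) {
  ids <- unique(groups)
  if (length(ids) < n_folds) stop("fewer groups than folds", call. = FALSE)
  withr_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      setNames(sample(rep_len(seq_len(n_folds), length(ids))), sample(ids))
    })
  })
}

rf_grid <- function(p) unique(c(1L, floor(sqrt(p)), floor(p / 3), 8L))

glmnet_lambda_seq <- function(x, y, alpha, task, n_lambda = 10) {
  fam <- if (task == "classification") "binomial" else "gaussian"
  fit <- glmnet::glmnet(x, y, family = fam, alpha = max(alpha, 0.01))
  lmax <- max(fit$lambda)
  exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
}

fit_learner <- function(x, y, algorithm, task, params, ntree = 500) {
  if (algorithm == "RF") {
    randomForest::randomForest(
      x = x, y = y, mtry = min(params$mtry, ncol(x)), ntree = ntree,
      importance = TRUE)
  } else {
    fam <- if (task == "classification") "binomial" else "gaussian"
    glmnet::glmnet(x, y, family = fam, alpha = params$alpha,
                   lambda = params$lambda, standardize = TRUE)
  }
}

predict_learner <- function(model, x, algorithm, task, params = NULL) {
  if (algorithm == "RF") {
    predict(model, x)
  } else if (task == "classification") {
    cls <- predict(model, x, s = params$lambda, type = "class")
    factor(drop(cls), levels = c("non_protected", "protected"))
  } else {
    drop(predict(model, x, s = params$lambda))
  }
}

#' Classification performance metrics
#'
#' Positive class is `protected`: precision is the fraction of truly
#' protective samples among those predicted protective, recall the fraction
#' of truly protective samples recovered, specificity the fraction of
#' non-protective samples correctly predicted.
#'
#' @param truth,pred Factors with levels `non_protected`, `protected`.
#' @return Tibble `accuracy`, `precision`, `recall`, `specificity`, `kappa`;
#'   a metric with an empty denominator is `NA`.
#' @export
classification_metrics <- function(truth, pred) {
  pos <- "protected"
  tp <- sum(truth == pos & pred == pos)
  fp <- sum(truth != pos & pred == pos)
  fn <- sum(truth == pos & pred != pos)
  tn <- sum(truth != pos & pred != pos)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tab <- table(factor(truth, levels = c("non_protected", "protected")),
               factor(pred, levels = c("non_protected", "protected")))
  tibble::tibble(
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    kappa = cohen_kappa(tab))
}

#' Tune one configuration by grouped repeated cross-validation
#'
#' Candidate hyperparameters (RF: features per split over `{1, sqrt(p), p/3,
#' 8}` with 500 trees; elastic net: mixing over `{0.1, 0.55, 1}` crossed with
#' 10 log-scale penalties) are scored by the mean tuning metric (kappa for
#' classification, RMSE for regression) across all `repeats x n_folds`
#' fold fits; the best candidate is then refitted on all training data.
#'
#' @param fm A [build_features()] matrix.
#' @param algorithm `"RF"` or `"GLMNet"`.
#' @param seed Integer seed driving fold assignment and the learners.
#' @param repeats,n_folds Cross-validation design (10 x 5).
#' @param ntree Trees per random forest.
#' @return List: `model` (final fit), `params`, `cv` (candidate scores),
#'   `algorithm`, `task`, `folds`.
#' @export
tune_and_fit <- function(fm, algorithm = c("RF", "GLMNet"), seed = 1,
                         repeats = 10, n_folds = 5, ntree = 500) {
  algorithm <- match.arg(algorithm)
  task <- fm$task
  folds <- make_grouped_folds(fm$group, n_folds, repeats, seed)
  candidates <- if (algorithm == "RF") {
    lapply(rf_grid(ncol(fm$x)), function(m) list(mtry = m))
  } else {
    lam_by_alpha <- lapply(c(0.1, 0.55, 1.0), function(a) {
      list(alpha = a, lambdas = glmnet_lambda_seq(fm$x, fm$response, a, task))
    })
    unlist(lapply(lam_by_alpha, function(al) {
      lapply(al$lambdas, function(l) list(alpha = al$alpha, lambda = l))
    }), recursive = FALSE)
  }

  scores <- matrix(NA_real_, length(candidates), repeats * n_folds)
  withr_seed(seed, {
    col <- 0L
    for (r in seq_len(repeats)) {
      assign_r <- folds[[r]]
      for (f in seq_len(n_folds)) {
        col <- col + 1L
        va_groups <- names(assign_r)[assign_r == f]
        va <- fm$group %in% va_groups
        if (!any(va) || all(va)) next
        x_tr <- fm$x[!va, , drop = FALSE]; y_tr <- fm$response[!va]
        x_va <- fm$x[va, , drop = FALSE]; y_va <- fm$response[va]
        if (task == "classification" && length(unique(y_tr)) < 2) next
        if (algorithm == "RF") {
          for (ci in seq_along(candidates)) {
            mod <- fit_learner(x_tr, y_tr, "RF", task, candidates[[ci]],
                               ntree = ntree)
            pred <- predict_learner(mod, x_va, "RF", task)
            scores[ci, col] <- if (task == "classification") {
              cohen_kappa(table(factor(y_va, levels = levels(fm$response)),
                                factor(pred, levels = levels(fm$response))))
            } else rmse(y_va, pred)
          }
        } else {
          for (a in unique(vapply(candidates, `[[`, numeric(1), "alpha"))) {
            lams <- vapply(Filter(function(c) c$alpha == a, candidates),
                           `[[`, numeric(1), "lambda")
            fam <- if (task == "classification") "binomial" else "gaussian"
            mod <- glmnet::glmnet(x_tr, y_tr, family = fam, alpha = a,
                                  lambda = lams, standardize = TRUE)
            for (l in lams) {
              ci <- which(vapply(candidates, function(c) {
                c$alpha == a && c$lambda == l
              }, logical(1)))
              pred <- predict_learner(mod, x_va, "GLMNet", task,
                                      list(lambda = l))
              scores[ci, col] <- if (task == "classification") {
                cohen_kappa(table(factor(y_va, levels = levels(fm$response)),
                                  factor(pred, levels = levels(fm$response))))
              } else rmse(y_va, pred)
            }
          }
        }
      }
    }
  })
  mean_score <- rowMeans(scores, na.rm = TRUE)
  best_i <- if (task == "classification") which.max(mean_score) else
    which.min(mean_score)
  best <- candidates[[best_i]]
  model <- withr_seed(seed + 1L, {
    if (algorithm == "GLMNet") {
      fam <- if (task == "classification") "binomial" else "gaussian"
      glmnet::glmnet(fm$x, fm$response, family = fam, alpha = best$alpha,
                     standardize = TRUE)
    } else {
      fit_learner(fm$x, fm$response, "RF", task, best, ntree = ntree)
    }
  })
  list(model = model, params = best, algorithm = algorithm, task = task,
       cv = tibble::tibble(candidate = seq_along(candidates),
                           mean_score = mean_score),
       folds = folds)
}

#' Evaluate a tuned model on the independent test screen
#'
#' @param fit A [tune_and_fit()] result.
#' @param test_fm Test-set [build_features()] matrix (its classes derive from
#'   the test experiment's own density minimum).
#' @return One-row tibble of metrics (classification) or `rmse` (regression).
#' @export
evaluate_on_test <- function(fit, test_fm) {
  pred <- predict_learner(fit$model, test_fm$x, fit$algorithm, fit$task,
                          fit$params)
  if (fit$task == "classification") {
    classification_metrics(test_fm$response, pred)
  } else {
    tibble::tibble(rmse = rmse(test_fm$response, pred))
  }
}

#' Monte-Carlo random-classifier baseline
#'
#' Each replicate assigns the positive class independently with probability
#' equal to the training positive prevalence; metrics are averaged across
#' replicates. Analytically, expected precision equals the test positive
#' prevalence and expected recall the assignment probability.
#'
#' @param train_classes,test_classes Factors with the class levels.
#' @param reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return One-row tibble of mean metrics plus the analytic expectations.
#' @export
random_classifier_baseline <- function(train_classes, test_classes,
                                       reps = 1000, seed = 1) {
  p <- mean(train_classes == "protected")
  n <- length(test_classes)
  mets <- withr_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(reps), function(r) {
      pred <- factor(ifelse(runif(n) < p, "protected", "non_protected"),
                     levels = levels(test_classes))
      classification_metrics(test_classes, pred)
    }))
  })
  out <- dplyr::summarise(mets, dplyr::across(dplyr::everything(),
                                              ~ mean(.x, na.rm = TRUE)))
  out$expected_precision <- mean(test_classes == "protected")
  out$expected_recall <- p
  out
}

#' Constant global-mean regression baseline
#'
#' RMSE of predicting the training-set global mean response for every test
#' row ("no model").
#'
#' @param train_response,test_response Numeric vectors.
#' @return RMSE (scalar).
#' @export
constant_mean_baseline <- function(train_response, test_response) {
  rmse(test_response, rep(mean(train_response), length(test_response)))
}

#' Relative strain importance of a fitted model
#'
#' Random forests: permutation importance (mean decrease in accuracy /
#' increase in MSE on out-of-bag data), negatives clipped at zero. Elastic
#' net: absolute coefficients on the standardized scale at the tuned
#' penalty. Each table is scaled so its maximum is 100.
#'
#' @param fit A [tune_and_fit()] result.
#' @param fm The feature matrix the model was fitted to.
#' @return Tibble `strain_id`, `importance` (0-100), `rank`.
#' @export
relative_importance <- function(fit, fm) {
  if (fit$algorithm == "RF") {
    imp <- randomForest::importance(fit$model, type = 1)[, 1]
  } else {
    beta <- as.matrix(coef(fit$model, s = fit$params$lambda))[-1, 1]
    imp <- abs(beta) * apply(fm$x, 2, stats::sd)
  }
  imp <- pmax(imp, 0)
  rel <- if (max(imp) > 0) 100 * imp / max(imp) else imp
  out <- tibble::tibble(strain_id = colnames(fm$x), importance = unname(rel))
  out$rank <- rank(-out$importance, ties.method = "min")
  out[order(out$rank), ]
}

#' Run one configuration across seeds
#'
#' @param train_fm,test_fm Feature matrices.
#' @param config One row of [enumerate_configs()].
#' @param seeds Integer vector (default 8 seeds).
#' @param repeats,n_folds,ntree Cross-validation and forest settings.
#' @return List: `performance` (per-seed metric tibble), `importance`
#'   (per-seed strain importances), `importance_median` (median across
#'   seeds).
#' @export
run_ml_config <- function(train_fm, test_fm, config, seeds = 1:8,
                          repeats = 10, n_folds = 5, ntree = 500) {
  perf <- list(); imps <- list()
  for (s in seeds) {
    fit <- tune_and_fit(train_fm, config$algorithm, seed = s,
                        repeats = repeats, n_folds = n_folds, ntree = ntree)
    met <- evaluate_on_test(fit, test_fm)
    met$seed <- s
    met$config_id <- config$config_id
    perf[[length(perf) + 1L]] <- met
    im <- relative_importance(fit, train_fm)
    im$seed <- s
    im$config_id <- config$config_id
    imps[[length(imps) + 1L]] <- im
  }
  imp <- dplyr::bind_rows(imps)
  imp_med <- dplyr::summarise(dplyr::group_by(imp, .data$strain_id),
                              importance = stats::median(.data$importance),
                              .groups = "drop")
  imp_med$rank <- rank(-imp_med$importance, ties.method = "min")
  list(performance = dplyr::bind_rows(perf), importance = imp,
       importance_median = imp_med[order(imp_med$rank), ])
}

#' Importance-rank stability under threshold resampling
#'
#' Re-fits the presence/individual random-forest classifier after
#' reclassifying the training rows with each candidate threshold and records
#' the importance ranking, reporting how stable the top strains are to the
#' uncertainty on the density-minimum position.
#'
#' @param fm Individual-level presence feature matrix carrying `value` (the
#'   per-row log10 pathogen level used for reclassification).
#' @param thresholds Numeric vector of candidate thresholds (e.g. from
#'   [sample_sensitivity_thresholds()]).
#' @param seed Integer seed (fixed across refits).
#' @param top_k Number of top strains whose rank stability is summarised.
#' @param repeats,n_folds,ntree Passed to [tune_and_fit()].
#' @return List: `ranks` (tibble threshold x strain rank), `top_sets` (list
#'   of top-`k` strain sets per refit), `skipped` (thresholds yielding an
#'   empty class).
#' @export
threshold_sensitivity_refit <- function(fm, thresholds, seed = 1, top_k = 3,
                                        repeats = 10, n_folds = 5,
                                        ntree = 500) {
  ranks <- list(); top_sets <- list(); skipped <- numeric()
  for (thr in thresholds) {
    cls <- factor(ifelse(fm$value < thr, "protected", "non_protected"),
                  levels = c("non_protected", "protected"))
    if (length(unique(cls)) < 2) {
      skipped <- c(skipped, thr)
      next
    }
    fm2 <- fm
    fm2$response <- cls
    fm2$task <- "classification"
    fit <- tune_and_fit(fm2, "RF", seed = seed, repeats = repeats,
                        n_folds = n_folds, ntree = ntree)
    im <- relative_importance(fit, fm2)
    im$threshold <- thr
    ranks[[length(ranks) + 1L]] <- im
    top_sets[[length(top_sets) + 1L]] <- im$strain_id[seq_len(top_k)]
  }
  list(ranks = dplyr::bind_rows(ranks), top_sets = top_sets, skipped = skipped)
}
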