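test_that("the configuration enumeration yields exactly the 12 analyses", {
  cfgs <- enumerate_configs()
  expect_equal(nrow(cfgs), 12)
  expect_equal(sum(cfgs$task == "classification"), 4)
  expect_equal(sum(cfgs$task == "regression"), 8)
  # classification only ever uses presence features
  expect_true(all(cfgs$features[cfgs$task == "classification"] == "presence"))
  expect_identical(cfgs$config_id, enumerate_configs()$config_id)
  expect_equal(anyDuplicated(cfgs[, c("algorithm", "task", "features", "level")]), 0L)
})

test_that("grouped folds never split a community across train and validation", {
  groups <- rep(sprintf("g%02d", 1:23), times = sample(2:5, 23, replace = TRUE))
  folds <- make_grouped_folds(groups, n_folds = 5, repeats = 10, seed = 3)
  expect_length(folds, 10)
  for (r in seq_along(folds)) {
    assign_r <- folds[[r]]
    # assignment is a function on groups, exhaustively
    expect_setequal(names(assign_r), unique(groups))
    expect_true(all(assign_r %in% 1:5))
    for (f in 1:5) {
      va_rows <- groups %in% names(assign_r)[assign_r == f]
      shared <- intersect(unique(groups[va_rows]), unique(groups[!va_rows]))
      expect_length(shared, 0)
    }
  }
  # 10 x 5 yields 50 fold evaluations
  expect_equal(sum(vapply(folds, function(a) length(unique(a)), numeric(1))), 50)
  expect_error(make_grouped_folds(c("a", "b"), n_folds = 5), "fewer groups")
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  # TP=14 FN=1 FP=4 TN=51
  truth <- factor(c(rep("protected", 15), rep("non_protected", 55)),
                  levels = c("non_protected", "protected"))
  pred <- factor(c(rep("protected", 14), "non_protected",
                   rep("protected", 4), rep("non_protected", 51)),
                 levels = c("non_protected", "protected"))
  m <- classification_metrics(truth, pred)
  expect_equal(m$recall, 14 / 15)
  expect_equal(m$precision, 14 / 18)
  expect_equal(m$specificity, 51 / 55)
  expect_equal(m$accuracy, 65 / 70)
  # perfect prediction
  p <- classification_metrics(truth, truth)
  expect_equal(unlist(p[c("precision", "recall", "specificity")]),
               c(precision = 1, recall = 1, specificity = 1))
  expect_equal(p$kappa, 1)
  # undefined denominators flagged as NA
  none_pred <- factor(rep("non_protected", 70),
                      levels = c("non_protected", "protected"))
  expect_true(is.na(classification_metrics(truth, none_pred)$precision))
})

test_that("kappa agrees with the independent e1071 computation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  t_ <- factor(sample(c("a", "b"), 60, replace = TRUE))
  p_ <- factor(sample(c("a", "b"), 60, replace = TRUE))
  tab <- table(t_, p_)
  expect_equal(syncomscreen:::cohen_kappa(tab),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("feature matrices have the documented shape and content", {
  scr <- generate_screen(generator_config(), seed = 31)
  train <- preprocess_screen(scr$train, "mean")
  thr <- screen_thresholds(train)
  fm_med <- build_features(train, "regression", "presence", "median")
  expect_equal(nrow(fm_med$x), 136)
  expect_equal(ncol(fm_med$x), 35)
  # every presence row has exactly k ones, consistent with membership
  expect_true(all(rowSums(fm_med$x) == 5))
  memb <- split(scr$communities$strain_id, scr$communities$community_id)
  i <- 17
  expect_setequal(colnames(fm_med$x)[fm_med$x[i, ] == 1],
                  memb[[fm_med$group[i]]])
  fm_ind <- build_features(train, "regression", "presence", "individual")
  expect_equal(nrow(fm_ind$x), 544)
  if (!any(is.na(thr$threshold))) {
    fm_cls <- build_features(train, "classification", "presence", "median",
                             thresholds = thr)
    expect_s3_class(fm_cls$response, "factor")
    expect_equal(levels(fm_cls$response), c("non_protected", "protected"))
  }
  expect_error(build_features(train, "classification", "colonization",
                              "median", thr), "presence")
  # colonization features carry log10 abundances, zero for absent strains
  fm_col <- build_features(train, "regression", "colonization", "median")
  expect_true(all(fm_col$x[fm_med$x == 0] == 0))
  expect_true(all(fm_col$x[fm_med$x == 1] > 0))
})

test_that("tuning with a single candidate returns it unchanged", {
  set.seed(10)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  fm <- structure(list(
    x = x, response = x[, 1] + rnorm(50, 0, 0.1),
    group = rep(sprintf("g%d", 1:10), each = 5),
    value = numeric(50), experiment = "e", task = "regression",
    features = "presence", level = "median"), class = "feature_matrix")
  with_mocked_bindings(
    rf_grid = function(p) 2L,
    {
      fit <- tune_and_fit(fm, "RF", seed = 1, repeats = 2, n_folds = 5,
                          ntree = 100)
      expect_equal(fit$params$mtry, 2L)
    })
})

test_that("baselines match their analytic expectations", {
  expect_equal(constant_mean_baseline(c(1, 1, 1), c(1, 1)), 0)
  expect_equal(constant_mean_baseline(c(-1, 1), c(-2, 2)), 2)
  # closed form sqrt(var + bias^2) on simulated responses
  set.seed(11)
  tr <- rnorm(4000, 1, 1.5)
  te <- rnorm(4000, 2, 1.5)
  expect_equal(constant_mean_baseline(tr, te),
               sqrt(1.5^2 + 1^2), tolerance = 0.07)
  # random classifier: precision -> test prevalence, recall -> train prevalence
  train_cls <- factor(rep(c("protected", "non_protected"), c(30, 70)),
                      levels = c("non_protected", "protected"))
  test_cls <- factor(rep(c("protected", "non_protected"), c(20, 60)),
                     levels = c("non_protected", "protected"))
  rb <- random_classifier_baseline(train_cls, test_cls, reps = 4000, seed = 2)
  expect_equal(rb$expected_precision, 0.25)
  expect_equal(rb$expected_recall, 0.3)
  # Monte-Carlo means converge to the analytic values
  expect_lt(abs(rb$recall - 0.3), 0.01)
  expect_lt(abs(rb$precision - 0.25), 0.02)
})

test_that("a single informative feature dominates the importance table", {
  set.seed(12)
  n <- 120
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("s", 1:20)))
  y <- 2 * x[, 7] + rnorm(n, 0, 0.3)
  fm <- structure(list(x = x, response = y,
                       group = rep(sprintf("g%d", 1:24), each = 5),
                       value = y, experiment = "e", task = "regression",
                       features = "presence", level = "median"),
                  class = "feature_matrix")
  fit <- tune_and_fit(fm, "RF", seed = 1, repeats = 2, n_folds = 5, ntree = 200)
  imp <- relative_importance(fit, fm)
  expect_equal(imp$strain_id[1], "s7")
  expect_equal(max(imp$importance), 100)
  fit_g <- tune_and_fit(fm, "GLMNet", seed = 1, repeats = 2, n_folds = 5)
  imp_g <- relative_importance(fit_g, fm)
  expect_equal(imp_g$strain_id[1], "s7")
  expect_equal(max(imp_g$importance), 100)
})

test_that("threshold-sensitivity refits are reproducible and skip empty classes", {
  set.seed(13)
  n <- 80
  x <- matrix(rbinom(n * 10, 1, 0.3), n, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  v <- 6 - 2 * x[, 3] + rnorm(n, 0, 0.4)
  fm <- structure(list(x = x, response = NULL,
                       group = rep(sprintf("g%d", 1:20), each = 4),
                       value = v, experiment = "e", task = "classification",
                       features = "presence", level = "individual"),
                  class = "feature_matrix")
  res <- threshold_sensitivity_refit(fm, thresholds = c(5, 5.2, -10),
                                     seed = 4, repeats = 2, ntree = 150)
  expect_equal(res$skipped, -10)
  expect_length(res$top_sets, 2)
  expect_true(all(vapply(res$top_sets, function(s) "s3" %in% s, logical(1))))
  res2 <- threshold_sensitivity_refit(fm, thresholds = c(5, 5), seed = 4,
                                      repeats = 2, ntree = 150)
  expect_identical(res2$top_sets[[1]], res2$top_sets[[2]])
})
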