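#!/usr/bin/env Rscript
# Stage 5 — supervised learning of protection outcomes: the model-algorithm
# combinations with grouped repeated cross-validation, test-set evaluation
# against baselines, and relative strain importances.
#
# By default the four box-median configurations are run across 8 seeds;
# set SYNCOM_ALL_CONFIGS=1 to run all 12 (slower).

library(syncomscreen)
dir.create("results", showWarnings = FALSE)
seed <- 20240915

scr <- generate_screen(generator_config(), seed = seed)
train <- preprocess_screen(scr$train, center = "mean")
test <- preprocess_screen(scr$test, center = "mean")
thr_train <- screen_thresholds(train)
thr_test <- fill_missing_thresholds(screen_thresholds(test), thr_train)
thr_train <- fill_missing_thresholds(thr_train, thr_test)

cfgs <- enumerate_configs()
if (!nzchar(Sys.getenv("SYNCOM_ALL_CONFIGS"))) {
  cfgs <- cfgs[cfgs$level == "median", ]
}
seeds <- 1:8

perf <- list(); imp <- list()
for (i in seq_len(nrow(cfgs))) {
  cfg_i <- cfgs[i, ]
  thr_arg <- if (cfg_i$task == "classification") thr_train else NULL
  tr_fm <- build_features(train, cfg_i$task, cfg_i$features, cfg_i$level,
                          thresholds = thr_arg)
  te_fm <- build_features(test, cfg_i$task, cfg_i$features, cfg_i$level,
                          thresholds = if (cfg_i$task == "classification")
                            thr_test else NULL)
  res <- run_ml_config(tr_fm, te_fm, cfg_i, seeds = seeds)
  p <- res$performance
  if (cfg_i$task == "classification") {
    base <- random_classifier_baseline(tr_fm$response, te_fm$response,
                                       seed = seed)
    cat(sprintf("%s %s/%s/%s: recall %.0f%% (random %.0f%%), precision %.0f%%, kappa %.2f\n",
                cfg_i$algorithm, cfg_i$task, cfg_i$features, cfg_i$level,
                100 * median(p$recall), 100 * base$recall,
                100 * median(p$precision), median(p$kappa)))
  } else {
    base <- constant_mean_baseline(tr_fm$response, te_fm$response)
    cat(sprintf("%s %s/%s/%s: RMSE %.2f (no-model %.2f)\n",
                cfg_i$algorithm, cfg_i$task, cfg_i$features, cfg_i$level,
                median(p$rmse), base))
  }
  perf[[cfg_i$config_id]] <- p
  im <- res$importance_median
  im$config_id <- cfg_i$config_id
  imp[[cfg_i$config_id]] <- im
}

write.csv(dplyr::bind_rows(perf), "results/performance.csv", row.names = FALSE)
imp_all <- dplyr::bind_rows(imp)
write.csv(imp_all, "results/importance_median.csv", row.names = FALSE)

overall <- dplyr::summarise(dplyr::group_by(imp_all, strain_id),
                            median_importance = median(importance),
                            .groups = "drop")
overall <- overall[order(-overall$median_importance), ]
cat("Top strains by median relative importance across analyses:\n")
print(head(overall, 5))
write.csv(overall, "results/importance_overall.csv", row.names = FALSE)

# sensitivity of the importance ranking to the class threshold: refit the
# individual-level presence classifier at thresholds drawn from the
# bootstrap distribution of density minima
agg <- aggregate_by_box(train)
agg <- agg[!(agg$treatment %in% train$controls), ]
e1 <- thr_train$experiment[1]
bs <- bootstrap_stability(agg$median_pathogen[agg$experiment == e1],
                          B = 500, seed = seed)
thr_draws <- sample_sensitivity_thresholds(bs, m = 10, seed = seed)
fm_ind <- build_features(train, "classification", "presence", "individual",
                         thr_train)
sens <- threshold_sensitivity_refit(fm_ind, thr_draws, seed = 1, repeats = 2)
stable <- vapply(sens$top_sets, function(s) {
  all(s %in% pr_strains(generator_config()))
}, logical(1))
cat(sprintf("Threshold sensitivity: implanted PR strains are the top 3 in %d of %d refits\n",
            sum(stable), length(stable)))
write.csv(sens$ranks, "results/importance_threshold_sensitivity.csv",
          row.names = FALSE)
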