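#' Standard preprocessing chain for a screen
#'
#' Partitions ambiguous counts, log10-transforms, normalizes pathogen
#' colonization by the per-experiment axenic controls, and flags Tukey-fence
#' outliers. Outliers are only flagged, never excluded automatically.
#'
#' @param dataset A `screen_data` on the linear scale.
#' @param center Normalization statistic: `"median"` for screen summaries,
#'   `"mean"` for regression targets.
#' @return The preprocessed `screen_data` (log10 scale).
#' @export
preprocess_screen <- function(dataset, center = c("mean", "median")) {
  center <- match.arg(center)
  dataset |>
    partition_ambiguous() |>
    log10_transform() |>
    normalize_pathogen(center = center) |>
    flag_outlier_plants()
}

#' Run the full screen analysis pipeline on one synthetic screen
#'
#' Executes the stages in dependency order: generate (or accept) a screen,
#' preprocess, community metrics, covariate associations, bimodality
#' thresholds and classes, the requested ML configurations with baselines
#' and importances, and the designated-strain group split. Stage tables are
#' optionally written as CSV.
#'
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @param screen Optional pre-generated [generate_screen()] result (overrides
#'   `config`/`seed` generation).
#' @param configs Rows of [enumerate_configs()] to run (default: the two
#'   presence/median configurations, one classification and one regression,
#'   per algorithm).
#' @param ml_seeds Seeds for each ML configuration.
#' @param ml_repeats,ml_folds Cross-validation design.
#' @param out_dir Optional output directory for stage CSVs.
#' @return List with every stage result.
#' @export
run_screen_pipeline <- function(config = generator_config(), seed = 1,
                                screen = NULL,
                                configs = NULL, ml_seeds = 1:8,
                                ml_repeats = 10, ml_folds = 5,
                                out_dir = NULL) {
  scr <- screen %||% generate_screen(config, seed)
  train <- preprocess_screen(scr$train, center = "mean")
  test <- preprocess_screen(scr$test, center = "mean")

  assoc_data <- prepare_association_data(scr$train, scr$tree)
  associations <- lapply(
    c(commensal = "commensal", evenness = "evenness",
      faith_pd = "faith_pd", weighted_mpd = "weighted_mpd"),
    function(cv) associate_covariate(assoc_data, cv))

  thr_train <- screen_thresholds(train)
  thr_test <- screen_thresholds(test)

  if (is.null(configs)) {
    all_cfg <- enumerate_configs()
    configs <- all_cfg[all_cfg$level == "median" & all_cfg$features == "presence", ]
  }
  ml <- list()
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    train_fm <- build_features(train, task = cfg$task, features = cfg$features,
                               level = cfg$level, thresholds = thr_train)
    test_fm <- build_features(test, task = cfg$task, features = cfg$features,
                              level = cfg$level, thresholds = thr_test)
    res <- run_ml_config(train_fm, test_fm, cfg, seeds = ml_seeds,
                         repeats = ml_repeats, n_folds = ml_folds)
    if (cfg$task == "classification") {
      res$baseline <- random_classifier_baseline(train_fm$response,
                                                 test_fm$response,
                                                 seed = seed)
    } else {
      res$baseline <- tibble::tibble(
        rmse = constant_mean_baseline(train_fm$response, test_fm$response))
    }
    ml[[cfg$config_id]] <- res
  }

  box_med <- aggregate_by_box(train)
  box_med <- box_med[!(box_med$treatment %in% train$controls), ]
  split <- split_pr_vs_others(
    scr$communities[scr$communities$community_id %in% box_med$community_id, ],
    pr_strains(config), box_med)

  out <- list(screen = scr, train = train, test = test,
              associations = associations,
              thresholds = list(train = thr_train, test = thr_test),
              ml = ml, group_split = split)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  w(res$screen$communities, "communities.csv")
  w(dplyr::bind_rows(res$associations), "association_fits.csv")
  w(dplyr::bind_rows(res$thresholds, .id = "set"), "thresholds.csv")
  perf <- dplyr::bind_rows(lapply(res$ml, `[[`, "performance"))
  if (nrow(perf)) w(perf, "performance.csv")
  imp <- dplyr::bind_rows(lapply(res$ml, `[[`, "importance"))
  if (nrow(imp)) w(imp, "importance.csv")
  w(res$group_split$groups, "groups.csv")
  invisible(out_dir)
}
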