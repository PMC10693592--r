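#' Enumerate the random-structure lattice for one covariate
#'
#' Fixed part is always `intercept + slope` for the covariate. Random
#' structures span the nested lattice over the two grouping factors
#' (experiment; box nested in experiment, one community per box): no random
#' effects; experiment intercept, optionally with a covariate slope; and each
#' of those combined with a box intercept or box intercept + slope. A box
#' term never appears without the experiment term, and a random slope always
#' comes with its intercept.
#'
#' @param covariate One of `"commensal"`, `"evenness"`, `"faith_pd"`,
#'   `"weighted_mpd"`.
#' @return Tibble of model specs: `model_id`, `covariate`, `experiment_terms`,
#'   `box_terms`, `formula` (string, `x` as covariate placeholder).
#' @export
enumerate_models <- function(covariate = c("commensal", "evenness",
                                           "faith_pd", "weighted_mpd")) {
  covariate <- match.arg(covariate)
  grid <- rbind(
    data.frame(experiment_terms = "none", box_terms = "none"),
    expand.grid(experiment_terms = c("intercept", "intercept+slope"),
                box_terms = c("none", "intercept", "intercept+slope"),
                stringsAsFactors = FALSE))
  term <- function(kind, group) switch(kind,
    "none" = NULL,
    "intercept" = sprintf("(1 | %s)", group),
    "intercept+slope" = sprintf("(1 + x | %s)", group))
  grid$formula <- vapply(seq_len(nrow(grid)), function(i) {
    parts <- c("y ~ x",
               term(grid$experiment_terms[i], "experiment"),
               term(grid$box_terms[i], "box_id"))
    paste(parts, collapse = " + ")
  }, character(1))
  tibble::tibble(model_id = sprintf("m%02d", seq_len(nrow(grid))),
                 covariate = covariate,
                 experiment_terms = grid$experiment_terms,
                 box_terms = grid$box_terms,
                 formula = grid$formula)
}

#' Fit one model of the lattice by REML
#'
#' Random-effect models are fitted with `lmerTest::lmer` (REML, Satterthwaite
#' degrees of freedom for the two-sided t test on the slope); the no-random
#' model with `nlme::gls` (REML), keeping the AIC comparable across the
#' lattice since the fixed part is identical throughout.
#'
#' @param spec One row of [enumerate_models()].
#' @param data Data frame with columns `y`, `x`, `experiment`, `box_id`.
#' @return One-row tibble: estimates, AIC, random-effect SDs, convergence and
#'   singularity flags.
#' @export
fit_association_model <- function(spec, data) {
  data <- data[stats::complete.cases(data[, c("y", "x")]), ]
  no_random <- spec$experiment_terms == "none" && spec$box_terms == "none"
  res <- list(beta_hat = NA_real_, se_beta = NA_real_, p_value = NA_real_,
              intercept = NA_real_, aic = NA_real_, residual_sd = NA_real_,
              sd_exp_intercept = NA_real_, sd_exp_slope = NA_real_,
              sd_box_intercept = NA_real_, sd_box_slope = NA_real_,
              converged = FALSE, singular = FALSE)
  if (no_random) {
    fit <- try(nlme::gls(y ~ x, data = data, method = "REML"), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      tt <- summary(fit)$tTable
      res$beta_hat <- tt["x", "Value"]
      res$se_beta <- tt["x", "Std.Error"]
      res$p_value <- tt["x", "p-value"]
      res$intercept <- tt["(Intercept)", "Value"]
      res$aic <- AIC(fit)
      res$residual_sd <- fit$sigma
      res$converged <- TRUE
    }
  } else {
    form <- stats::as.formula(spec$formula)
    conv_warning <- FALSE
    fit <- withCallingHandlers(
      suppressMessages(
        try(lmerTest::lmer(form, data = data, REML = TRUE), silent = TRUE)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          conv_warning <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    if (!inherits(fit, "try-error")) {
      cf <- try(summary(fit)$coefficients, silent = TRUE)
      if (!inherits(cf, "try-error") && "x" %in% rownames(cf)) {
        res$beta_hat <- cf["x", "Estimate"]
        res$se_beta <- cf["x", "Std. Error"]
        res$p_value <- cf["x", "Pr(>|t|)"]
        res$intercept <- cf["(Intercept)", "Estimate"]
        res$aic <- AIC(fit)
        res$residual_sd <- stats::sigma(fit)
        vc <- as.data.frame(lme4::VarCorr(fit))
        pick <- function(grp, var) {
          hit <- vc$grp == grp & !is.na(vc$var1) & vc$var1 == var & is.na(vc$var2)
          if (any(hit)) vc$sdcor[hit][1] else NA_real_
        }
        res$sd_exp_intercept <- pick("experiment", "(Intercept)")
        res$sd_exp_slope <- pick("experiment", "x")
        res$sd_box_intercept <- pick("box_id", "(Intercept)")
        res$sd_box_slope <- pick("box_id", "x")
        res$singular <- lme4::isSingular(fit)
        res$converged <- !conv_warning
      }
    }
  }
  dplyr::bind_cols(tibble::as_tibble(spec), tibble::as_tibble(res))
}

#' Fit the whole lattice and select by delta AIC
#'
#' @param data Data frame with `y`, `x`, `experiment`, `box_id`.
#' @param covariate Covariate label (sets the lattice).
#' @param center Center `x` before fitting (done for commensal colonization
#'   so the intercept reads as the expected pathogen level at mid commensal
#'   levels).
#' @return Tibble of fits with `delta_aic` and logical `selected`
#'   (`delta_aic < 4` among converged fits).
#' @export
fit_model_set <- function(data, covariate = "commensal",
                          center = identical(covariate, "commensal")) {
  if (center) data$x <- data$x - mean(data$x, na.rm = TRUE)
  specs <- enumerate_models(covariate)
  fits <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(i) {
    fit_association_model(specs[i, ], data)
  }))
  select_models(fits)
}

#' Apply the delta-AIC selection rule
#'
#' @param fits Tibble of fits (needs `aic`, `converged`).
#' @param delta Selection threshold on the AIC difference to the best model.
#' @return `fits` with `delta_aic` and `selected` columns; selection is
#'   independent of row order.
#' @export
select_models <- function(fits, delta = 4) {
  ok <- fits$converged & is.finite(fits$aic)
  if (!any(ok)) stop("no converged model to select from", call. = FALSE)
  best <- min(fits$aic[ok])
  fits$delta_aic <- ifelse(ok, fits$aic - best, NA_real_)
  fits$selected <- ok & fits$delta_aic < delta
  fits
}

#' Best-model slope of a fitted set
#' @param fits Output of [fit_model_set()].
#' @return Named list: `beta_hat`, `se_beta`, `p_value`, `model_id` of the
#'   minimum-AIC converged model.
#' @export
best_model_slope <- function(fits) {
  sel <- fits[fits$converged & is.finite(fits$aic), ]
  best <- sel[which.min(sel$aic), ]
  list(beta_hat = best$beta_hat, se_beta = best$se_beta,
       p_value = best$p_value, model_id = best$model_id)
}

#' Per-plant analysis table for the association stage
#'
#' Joins log10 pathogen colonization with the three community covariates:
#' centered-ready log10 total commensal colonization, realized Pielou
#' evenness, realized weighted mpd, and inoculum Faith PD, plus the
#' community-level exclusion flags used by the sensitivity subsets. Controls
#' and excluded plants are dropped.
#'
#' @param dataset A `screen_data` on the linear scale (floors in place).
#' @param tree Strain phylogeny.
#' @return Tibble, one row per retained plant.
#' @export
prepare_association_data <- function(dataset, tree) {
  stopifnot(inherits(dataset, "screen_data"))
  if (dataset$scale != "linear") stop("start from the linear scale", call. = FALSE)
  part <- partition_ambiguous(dataset)
  commensal <- total_commensal(part)
  realized <- community_metrics(part, tree, mode = "realized")
  inoc <- community_metrics(part, tree, mode = "inoculum")
  logd <- log10_transform(part)
  pl <- logd$plants
  pl <- pl[!(pl$treatment %in% logd$controls) & !pl$excluded &
             !is.na(pl$pathogen_cfu), ]
  out <- dplyr::left_join(pl, commensal, by = "plant_id")
  out <- dplyr::left_join(out,
    realized[, c("plant_id", "evenness", "weighted_mpd", "n_detected",
                 "has_below_detection", "has_ambiguous")], by = "plant_id")
  out <- dplyr::left_join(out, inoc, by = "community_id")
  out$commensal <- log10(out$total_cfu)
  # community-level flags: any plant of the community affected
  flags <- dplyr::summarise(
    dplyr::group_by(out, .data$community_id),
    comm_below_detection = any(.data$has_below_detection),
    comm_ambiguous = any(.data$has_ambiguous), .groups = "drop")
  out <- dplyr::left_join(out, flags, by = "community_id")
  out$y <- out$pathogen_cfu
  tibble::as_tibble(out)
}

#' Main and strict analysis subsets for one covariate
#'
#' Evenness and weighted-mpd analyses exclude communities with ambiguous
#' counts (the metric needs each member's abundance); their sensitivity
#' subsets additionally exclude communities with any strain below the
#' detection level. Commensal and inoculum-diversity analyses use all
#' communities in the main run, with the same stricter subset for
#' sensitivity.
#'
#' @param data Output of [prepare_association_data()].
#' @param covariate Covariate name.
#' @return List of tibbles `main`, `strict`, plus `n_main`, `n_strict`
#'   (community counts).
#' @export
sensitivity_subsets <- function(data, covariate = c("commensal", "evenness",
                                                    "faith_pd", "weighted_mpd")) {
  covariate <- match.arg(covariate)
  needs_unambiguous <- covariate %in% c("evenness", "weighted_mpd")
  main <- if (needs_unambiguous) data[!data$comm_ambiguous, ] else data
  strict <- main[!main$comm_below_detection & !main$comm_ambiguous, ]
  list(main = main, strict = strict,
       n_main = length(unique(main$community_id)),
       n_strict = length(unique(strict$community_id)))
}

#' Association of pathogen colonization with one community covariate
#'
#' Runs the full lattice on the chosen subset, with centering for the
#' commensal covariate, and returns the selected fits.
#'
#' @param data Output of [prepare_association_data()].
#' @param covariate Covariate name.
#' @param subset `"main"` or `"strict"`.
#' @return Tibble of fits (see [fit_model_set()]).
#' @export
associate_covariate <- function(data,
                                covariate = c("commensal", "evenness",
                                              "faith_pd", "weighted_mpd"),
                                subset = c("main", "strict")) {
  covariate <- match.arg(covariate)
  subset <- match.arg(subset)
  subs <- sensitivity_subsets(data, covariate)
  d <- subs[[subset]]
  d <- d[, c("y", covariate, "experiment", "box_id")]
  names(d)[2] <- "x"
  fit_model_set(d, covariate)
}
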