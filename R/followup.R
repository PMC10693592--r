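#' Split communities into a designated-strain group and the rest
#'
#' The positive group contains every community with at least one designated
#' strain (e.g. the validated pathogen-reducing strains); all other
#' communities form the "Others" group. Group medians are medians of the
#' per-box median pathogen levels.
#'
#' @param communities Named list of strain vectors, or a long membership
#'   tibble (`community_id`, `strain_id`).
#' @param pr_ids Character vector of designated strains (non-empty).
#' @param box_medians Tibble `community_id`, `median_pathogen` (one row per
#'   community/box).
#' @return List of class `group_split`: `groups` (tibble `community_id`,
#'   `group`), `median_pr`, `median_others`, `n_pr`, `n_others`.
#' @export
split_pr_vs_others <- function(communities, pr_ids, box_medians) {
  if (length(pr_ids) == 0) stop("pr_ids must be non-empty", call. = FALSE)
  comm_list <- if (is.list(communities) && !is.data.frame(communities)) {
    communities
  } else {
    split(communities$strain_id, communities$community_id)
  }
  grp <- vapply(comm_list, function(m) any(pr_ids %in% m), logical(1))
  groups <- tibble::tibble(
    community_id = names(comm_list),
    group = unname(ifelse(grp, "PR Strains", "Others")))
  merged <- dplyr::inner_join(groups, box_medians, by = "community_id")
  med <- function(g) {
    v <- merged$median_pathogen[merged$group == g]
    if (length(v)) stats::median(v) else NA_real_
  }
  structure(list(groups = groups,
                 median_pr = med("PR Strains"), median_others = med("Others"),
                 n_pr = sum(grp), n_others = sum(!grp)),
            class = "group_split")
}

#' Communities in the low tail of the "Others" group
#'
#' @param split A [split_pr_vs_others()] result.
#' @param box_medians Tibble `community_id`, `median_pathogen`.
#' @param threshold Numeric cutoff, typically the experiment's protection
#'   class boundary.
#' @return Character vector of "Others" community ids with median below the
#'   threshold.
#' @export
tail_communities <- function(split, box_medians, threshold) {
  others <- split$groups$community_id[split$groups$group == "Others"]
  sub <- box_medians[box_medians$community_id %in% others, ]
  sort(sub$community_id[sub$median_pathogen < threshold])
}

#' Strain membership frequency in a set of communities
#'
#' @param communities Named list of strain vectors or membership tibble.
#' @param ids Optional subset of community ids to count over.
#' @param pool Optional [strain_pool()] to report zero counts.
#' @return Tibble `strain_id`, `count`.
#' @export
strain_frequency_in <- function(communities, ids = NULL, pool = NULL) {
  comm_list <- if (is.list(communities) && !is.data.frame(communities)) {
    communities
  } else {
    split(communities$strain_id, communities$community_id)
  }
  if (!is.null(ids)) comm_list <- comm_list[intersect(names(comm_list), ids)]
  counts <- table(unlist(comm_list, use.names = FALSE))
  strain_ids <- if (is.null(pool)) sort(names(counts)) else pool$strain_ids
  tibble::tibble(
    strain_id = strain_ids,
    count = as.integer(ifelse(strain_ids %in% names(counts),
                              counts[strain_ids], 0L)))
}

#' Compact letter display by insert-and-absorb
#'
#' Builds letter groups from a pairwise significance matrix: treatments
#' sharing no letter differ significantly; every non-significant pair shares
#' at least one letter.
#'
#' @param signif_mat Logical symmetric matrix (TRUE = significantly
#'   different) with treatment dimnames.
#' @return Named character vector of letter strings.
#' @export
letter_display <- function(signif_mat) {
  trts <- rownames(signif_mat)
  cols <- list(trts) # start: one group holding everything
  pairs <- which(upper.tri(signif_mat) & signif_mat, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- trts[pairs[k, 1]]; b <- trts[pairs[k, 2]]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  cols <- cols[order(vapply(cols, function(c) match(c[1], trts), numeric(1)))]
  letters_out <- setNames(rep("", length(trts)), trts)
  for (i in seq_along(cols)) {
    lab <- letters[(i - 1) %% 26 + 1]
    if (i > 26) lab <- paste0(lab, (i - 1) %/% 26)
    for (t in cols[[i]]) letters_out[t] <- paste0(letters_out[t], lab)
  }
  letters_out
}

#' Pairwise treatment contrasts for a validation experiment
#'
#' Pathogen colonization is averaged per box first (one value per box, so
#' the grouping structure disappears), then modelled with the inoculation
#' treatment as fixed effect and the enumerated random structures for the
#' experimental round (none; random intercept; random intercept + slope).
#' The minimum-AIC converged model provides two-sided t contrasts for every
#' declared treatment pair; p values are Bonferroni-corrected over the
#' declared family and turned into significance letters at adjusted 0.05.
#'
#' @param dataset A `screen_data` on the log10 scale (validation experiment;
#'   `experiment` holds the round).
#' @param family Optional two-column matrix / data frame of treatment pairs;
#'   default all pairwise combinations of non-excluded treatments.
#' @param exclude_treatments Treatments left out of the model (e.g.
#'   non-infected controls).
#' @param alpha Significance level on the adjusted scale.
#' @return List of class `contrast_result`: `contrasts` tibble (`a`, `b`,
#'   `estimate`, `se`, `p_raw`, `p_bonferroni`), `family_size`, `letters`,
#'   `model` (selected fits tibble), `box_means`.
#' @export
validation_contrasts <- function(dataset, family = NULL,
                                 exclude_treatments = c("axenic-NI"),
                                 alpha = 0.05) {
  stopifnot(inherits(dataset, "screen_data"), dataset$scale == "log10")
  pl <- dataset$plants
  pl <- pl[!pl$excluded & !is.na(pl$pathogen_cfu) &
             !(pl$treatment %in% exclude_treatments), ]
  box_means <- dplyr::summarise(
    dplyr::group_by(pl, .data$box_id, .data$experiment, .data$treatment),
    y = mean(.data$pathogen_cfu), .groups = "drop")
  n_boxes <- table(box_means$treatment)
  single_box <- names(n_boxes)[n_boxes < 2]
  box_means$treatment <- factor(box_means$treatment)

  fits <- list()
  gls_fit <- try(nlme::gls(y ~ treatment, data = box_means, method = "REML"),
                 silent = TRUE)
  if (!inherits(gls_fit, "try-error")) {
    fits[["none"]] <- list(fit = gls_fit, aic = AIC(gls_fit))
  }
  for (spec in c("(1 | experiment)", "(1 | experiment) + (0 + treatment | experiment)")) {
    form <- stats::as.formula(paste("y ~ treatment +", spec))
    fit <- suppressWarnings(suppressMessages(
      try(lmerTest::lmer(form, data = box_means, REML = TRUE), silent = TRUE)))
    if (!inherits(fit, "try-error")) {
      fits[[spec]] <- list(fit = fit, aic = AIC(fit))
    }
  }
  if (!length(fits)) stop("no model could be fitted", call. = FALSE)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]$fit

  emm <- emmeans::emmeans(best, "treatment", data = as.data.frame(box_means))
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  split_names <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  prs$a <- gsub("^\\(|\\)$", "", vapply(split_names, `[[`, character(1), 1))
  prs$b <- gsub("^\\(|\\)$", "", vapply(split_names, `[[`, character(1), 2))

  trts <- levels(box_means$treatment)
  if (is.null(family)) {
    cmb <- utils::combn(setdiff(trts, single_box), 2)
    family <- data.frame(a = cmb[1, ], b = cmb[2, ])
  } else {
    family <- as.data.frame(family)
    names(family)[1:2] <- c("a", "b")
  }
  m <- nrow(family)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  prs$key <- key(prs$a, prs$b)
  family$key <- key(family$a, family$b)
  hit <- match(family$key, prs$key)
  if (anyNA(hit)) stop("family pair not present among model treatments", call. = FALSE)
  out <- tibble::tibble(
    a = family$a, b = family$b,
    estimate = prs$estimate[hit], se = prs$SE[hit],
    p_raw = prs$p.value[hit],
    p_bonferroni = pmin(1, prs$p.value[hit] * m))

  fam_trts <- unique(c(out$a, out$b))
  sig <- matrix(FALSE, length(fam_trts), length(fam_trts),
                dimnames = list(fam_trts, fam_trts))
  for (i in seq_len(nrow(out))) {
    s <- out$p_bonferroni[i] < alpha
    sig[out$a[i], out$b[i]] <- s
    sig[out$b[i], out$a[i]] <- s
  }
  structure(list(contrasts = out, family_size = m,
                 letters = letter_display(sig),
                 significance_matrix = sig,
                 best_model = names(which.min(aics)),
                 model_aics = aics,
                 skipped_treatments = single_box,
                 box_means = box_means),
            class = "contrast_result")
}
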