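#' Plant-level screen dataset
#'
#' Container for one screen (or validation experiment): plant-level pathogen
#' measurements plus long-format per-strain commensal colonization, with the
#' community membership table and control treatment labels. Values start on
#' the linear CFU-per-gram scale; [log10_transform()] moves the whole dataset
#' to log10 and sets a scale marker so the transform cannot be applied twice.
#'
#' @param plants Tibble: `experiment`, `box_id`, `treatment`, `community_id`
#'   (NA for controls), `plant_id`, `fresh_weight_mg`, `pathogen_cfu`,
#'   `excluded`, `exclude_reason`.
#' @param strains Tibble: `plant_id`, `strain_id`, `cfu_per_g`, `flag`
#'   (`detected`, `below_detection` or `ambiguous`), `ambiguity_group`.
#'   Rows of one ambiguity group carry the *pooled* count until
#'   [partition_ambiguous()] splits it.
#' @param communities Long membership tibble (`community_id`, `strain_id`).
#' @param controls Character vector of treatment labels that are controls.
#' @param scale `"linear"` or `"log10"`.
#' @param ambiguity_partitioned Whether pooled ambiguous counts were already
#'   split equally among their group members.
#' @return A `screen_data` object.
#' @export
screen_data <- function(plants, strains, communities,
                        controls = character(), scale = "linear",
                        ambiguity_partitioned = FALSE) {
  plants <- tibble::as_tibble(plants)
  strains <- tibble::as_tibble(strains)
  communities <- tibble::as_tibble(communities)
  needed <- c("experiment", "box_id", "treatment", "community_id", "plant_id",
              "pathogen_cfu", "excluded")
  missing <- setdiff(needed, names(plants))
  if (length(missing)) stop("plants table lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!all(c("plant_id", "strain_id", "cfu_per_g", "flag") %in% names(strains))) {
    stop("strains table lacks required columns", call. = FALSE)
  }
  non_control <- plants[!(plants$treatment %in% controls), ]
  if (any(is.na(non_control$community_id))) {
    stop("non-control records must map to a community", call. = FALSE)
  }
  structure(list(plants = plants, strains = strains,
                 communities = communities, controls = controls,
                 scale = scale, ambiguity_partitioned = ambiguity_partitioned),
            class = "screen_data")
}

#' @export
print.screen_data <- function(x, ...) {
  cat(sprintf(
    "<screen_data> %d plants / %d boxes / %d communities (%s scale)\n",
    nrow(x$plants), length(unique(x$plants$box_id)),
    length(unique(stats::na.omit(x$plants$community_id))), x$scale))
  invisible(x)
}

#' Log10-transform all colonization values
#'
#' All CFU measurements are log10-transformed prior to analysis. Detection
#' floors must already be in place so every value is strictly positive; the
#' scale marker guards against accidental double transformation.
#'
#' @param dataset A `screen_data` on the linear scale.
#' @return The dataset with `pathogen_cfu` and `cfu_per_g` on the log10 scale.
#' @export
log10_transform <- function(dataset) {
  stopifnot(inherits(dataset, "screen_data"))
  if (dataset$scale == "log10") stop("dataset is already log10-scaled", call. = FALSE)
  bad <- c(dataset$plants$pathogen_cfu, dataset$strains$cfu_per_g)
  if (any(!is.na(bad) & bad <= 0)) {
    stop("nonpositive CFU value; apply detection floors first", call. = FALSE)
  }
  dataset$plants$pathogen_cfu <- log10(dataset$plants$pathogen_cfu)
  dataset$strains$cfu_per_g <- log10(dataset$strains$cfu_per_g)
  dataset$scale <- "log10"
  dataset
}

#' Detection floor for undetected strains
#'
#' Undetected strains are recorded as a count of 0.09 at the lowest counted
#' dilution, then converted to CFU per gram with the same dilution-and-weight
#' arithmetic as real counts, so the floor is strictly positive and the log10
#' transform is always defined.
#'
#' @param count_table Tibble with `raw_count` (NA or 0 = undetected) and
#'   `conversion` (CFU-per-gram per counted colony at the lowest counted
#'   dilution, i.e. dilution factor / (plated volume x plant weight)).
#' @param floor_count Raw-count sentinel for undetected strains (0.09).
#' @return The table with `cfu_per_g` and `flag` columns filled in.
#' @export
apply_detection_floor <- function(count_table, floor_count = 0.09) {
  count_table <- tibble::as_tibble(count_table)
  if (!all(c("raw_count", "conversion") %in% names(count_table))) {
    stop("count table needs raw_count and conversion columns", call. = FALSE)
  }
  if (any(is.na(count_table$conversion))) {
    stop("missing dilution/weight conversion metadata", call. = FALSE)
  }
  undet <- is.na(count_table$raw_count) | count_table$raw_count == 0
  count_table$flag <- ifelse(undet, "below_detection", "detected")
  eff <- ifelse(undet, floor_count, count_table$raw_count)
  count_table$cfu_per_g <- eff * count_table$conversion
  count_table
}

#' Partition pooled ambiguous counts equally
#'
#' Strains that cannot be distinguished share one pooled CFU count; the pooled
#' value is split equally between the group members on the linear scale so
#' total commensal colonization is conserved exactly.
#'
#' @param dataset A `screen_data` on the linear scale.
#' @return The dataset with per-strain values for ambiguous groups and the
#'   `ambiguity_partitioned` marker set.
#' @export
partition_ambiguous <- function(dataset) {
  stopifnot(inherits(dataset, "screen_data"))
  if (dataset$scale != "linear") stop("partition on the linear scale", call. = FALSE)
  if (dataset$ambiguity_partitioned) return(dataset)
  st <- dataset$strains
  amb <- !is.na(st$ambiguity_group)
  if (any(amb)) {
    sizes <- stats::ave(rep(1, sum(amb)), st$ambiguity_group[amb], FUN = sum)
    if (any(sizes < 2)) stop("ambiguous group of size < 2", call. = FALSE)
    st$cfu_per_g[amb] <- st$cfu_per_g[amb] / sizes
  }
  dataset$strains <- st
  dataset$ambiguity_partitioned <- TRUE
  dataset
}

#' Total commensal colonization per plant
#'
#' Sum of the colonization of the individual community strains (linear scale);
#' the pathogen is never part of this sum. Before partitioning, each ambiguous
#' group's pooled count enters once; afterwards the equal shares sum to the
#' same value. Plants without strains (axenic) get `n_strains = 0` and a zero
#' total.
#'
#' @param dataset A `screen_data` on the linear scale.
#' @return Tibble `plant_id`, `total_cfu`, `n_strains`.
#' @export
total_commensal <- function(dataset) {
  stopifnot(inherits(dataset, "screen_data"))
  if (dataset$scale != "linear") stop("total commensal needs the linear scale", call. = FALSE)
  st <- dataset$strains
  if (!dataset$ambiguity_partitioned && any(!is.na(st$ambiguity_group))) {
    # count each pooled group once: keep the first row per (plant, group)
    keep <- !duplicated(paste(st$plant_id, st$ambiguity_group)) |
      is.na(st$ambiguity_group)
    st <- st[keep, ]
  }
  sums <- dplyr::summarise(dplyr::group_by(st, .data$plant_id),
                           total_cfu = sum(.data$cfu_per_g),
                           n_strains = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(
    tibble::tibble(plant_id = dataset$plants$plant_id), sums, by = "plant_id")
  out$total_cfu[is.na(out$total_cfu)] <- 0
  out$n_strains[is.na(out$n_strains)] <- 0L
  out
}

#' Normalize pathogen colonization by the axenic infected controls
#'
#' Within each experiment the chosen statistic (median for screen summaries,
#' mean for regression targets) of the axenic infected controls is subtracted
#' from every log10 pathogen value, yielding the normalized pathogen
#' reduction.
#'
#' @param dataset A `screen_data` on the log10 scale.
#' @param center `"median"` or `"mean"`.
#' @param axenic_label Treatment label of the axenic infected controls.
#' @return The dataset with a `pathogen_norm` column added to `plants`.
#' @export
normalize_pathogen <- function(dataset, center = c("median", "mean"),
                               axenic_label = "axenic") {
  stopifnot(inherits(dataset, "screen_data"))
  center <- match.arg(center)
  if (dataset$scale != "log10") stop("normalize on the log10 scale", call. = FALSE)
  pl <- dataset$plants
  ax <- pl[pl$treatment == axenic_label & !pl$excluded & !is.na(pl$pathogen_cfu), ]
  stat_fun <- if (center == "median") stats::median else mean
  refs <- tapply(ax$pathogen_cfu, ax$experiment, stat_fun)
  missing <- setdiff(unique(pl$experiment), names(refs))
  if (length(missing)) {
    stop("experiment lacking axenic infected controls: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pl$pathogen_norm <- pl$pathogen_cfu - as.numeric(refs[pl$experiment])
  dataset$plants <- pl
  dataset
}

#' Tukey-fence outlier flags
#'
#' A value outside the closed interval `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of its
#' group is flagged. Quartiles use linear interpolation between order
#' statistics (type 7). Flags never exclude by themselves: exclusion requires
#' a recorded experimental reason.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (e.g. treatment), same length.
#' @return Logical vector of flags.
#' @export
flag_outliers <- function(values, groups = rep(1L, length(values))) {
  stopifnot(length(values) == length(groups))
  out <- logical(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(values))
    if (length(idx) < 2) next
    q <- stats::quantile(values[idx], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    out[idx] <- values[idx] < lo | values[idx] > hi
  }
  out
}

#' Flag outlier plants by treatment within experiment
#' @param dataset A `screen_data` on the log10 scale.
#' @return The dataset with a logical `outlier` column on `plants`.
#' @export
flag_outlier_plants <- function(dataset) {
  stopifnot(inherits(dataset, "screen_data"), dataset$scale == "log10")
  pl <- dataset$plants
  pl$outlier <- flag_outliers(pl$pathogen_cfu,
                              paste(pl$experiment, pl$treatment))
  dataset$plants <- pl
  dataset
}

#' Exclude plants for a recorded experimental reason
#' @param dataset A `screen_data`.
#' @param plant_ids Plants to exclude.
#' @param reason One of `"contamination"`, `"disturbed"`.
#' @export
exclude_plants <- function(dataset, plant_ids,
                           reason = c("contamination", "disturbed")) {
  reason <- match.arg(reason)
  sel <- dataset$plants$plant_id %in% plant_ids
  dataset$plants$excluded[sel] <- TRUE
  dataset$plants$exclude_reason[sel] <- reason
  dataset
}

#' Aggregate plant measurements per box
#'
#' Median log10 pathogen colonization per box (one community per box), after
#' exclusions. `pathogen_norm` is aggregated alongside when present.
#'
#' @param dataset A `screen_data` on the log10 scale.
#' @return Tibble `box_id`, `experiment`, `treatment`, `community_id`,
#'   `median_pathogen`, optional `median_pathogen_norm`, `n_plants`.
#' @export
aggregate_by_box <- function(dataset) {
  stopifnot(inherits(dataset, "screen_data"))
  if (dataset$scale != "log10") stop("aggregate on the log10 scale", call. = FALSE)
  pl <- dataset$plants
  pl <- pl[!pl$excluded & !is.na(pl$pathogen_cfu), ]
  if (nrow(pl) == 0) stop("no usable plants to aggregate", call. = FALSE)
  grouped <- dplyr::group_by(pl, .data$box_id, .data$experiment,
                             .data$treatment, .data$community_id)
  out <- dplyr::summarise(
    grouped,
    median_pathogen = stats::median(.data$pathogen_cfu),
    median_pathogen_norm = if ("pathogen_norm" %in% names(pl)) {
      stats::median(.data$pathogen_norm)
    } else NA_real_,
    n_plants = dplyr::n(), .groups = "drop")
  out
}

#' @importFrom dplyr .data
NULL
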