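#' Gaussian kernel density estimate of pathogen colonization
#'
#' Silverman's rule-of-thumb bandwidth, 512-point regular grid spanning the
#' data range plus three bandwidths on each side.
#'
#' @param values Numeric vector (log10 CFU/g), length >= 10.
#' @param bw Optional bandwidth override.
#' @return List of class `density_estimate`: `grid`, `density`, `bandwidth`,
#'   `n`.
#' @export
estimate_density <- function(values, bw = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("degenerate sample: all values equal", call. = FALSE)
  bw <- bw %||% stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512, cut = 3)
  structure(list(grid = d$x, density = d$y, bandwidth = bw,
                 n = length(values)), class = "density_estimate")
}

# Interior local extrema of a density curve (indices into the grid).
local_extrema <- function(y) {
  dy <- diff(y)
  s <- sign(dy)
  s[s == 0] <- 1L
  turns <- diff(s)
  list(minima = which(turns == 2) + 1L,
       maxima = which(turns == -2) + 1L)
}

#' Global minimum separating the two main modes
#'
#' Among interior local minima of the density curve, returns the one with the
#' lowest density located between the two highest-density modes; when no
#' interior local minimum exists (unimodal curve) the absence is reported,
#' not raised. Ties break toward lower density, then lower location. Modes
#' below `min_mode_height` (as a fraction of the highest peak) are treated as
#' sampling ripples, not modes of interest.
#'
#' @param de A [estimate_density()] result.
#' @param min_mode_height Minimum relative height for a mode to count.
#' @param min_valley_depth Minimum relative depth of the separating valley:
#'   the minimum must lie at least this fraction below the smaller of the two
#'   flanking modes, so crown ripples of a unimodal curve do not count.
#' @return The threshold location (numeric) or `NULL` when none exists.
#' @export
find_global_minimum <- function(de, min_mode_height = 0.1,
                                min_valley_depth = 0.1) {
  stopifnot(inherits(de, "density_estimate"))
  ext <- local_extrema(de$density)
  keep <- de$density[ext$maxima] >= min_mode_height * max(de$density)
  ext$maxima <- ext$maxima[keep]
  if (length(ext$minima) == 0 || length(ext$maxima) < 2) return(NULL)
  # positions of the two highest modes
  top2 <- ext$maxima[order(de$density[ext$maxima], decreasing = TRUE)[1:2]]
  lo <- min(de$grid[top2]); hi <- max(de$grid[top2])
  cand <- ext$minima[de$grid[ext$minima] > lo & de$grid[ext$minima] < hi]
  if (length(cand) == 0) return(NULL)
  cand <- cand[order(de$density[cand], de$grid[cand])]
  best <- cand[1]
  if (de$density[best] > (1 - min_valley_depth) * min(de$density[top2])) {
    return(NULL)
  }
  de$grid[best]
}

#' Bootstrap stability of the density minimum
#'
#' Resamples the values with replacement `B` times; for each replicate a
#' density curve is estimated and a local minimum is searched inside the
#' reference region (full-data minimum +/- `region_halfwidth` by default).
#' The fraction of replicates with such a minimum measures how robust the
#' bimodal split is to sampling noise.
#'
#' @param values Numeric vector.
#' @param B Number of bootstrap replicates.
#' @param region Length-2 numeric region in which minima count as detected;
#'   default derives from the full-data minimum.
#' @param region_halfwidth Half-width of the default region (log10 units).
#' @param seed Integer seed.
#' @return List of class `bootstrap_stability`: `B`, `minima` (one per
#'   replicate where found), `detection_fraction`, `p5`, `p95`, `region`.
#' @export
bootstrap_stability <- function(values, B = 1000, region = NULL,
                                region_halfwidth = 0.5, seed = 1) {
  values <- values[!is.na(values)]
  if (is.null(region)) {
    thr <- find_global_minimum(estimate_density(values))
    if (is.null(thr)) stop("no full-data minimum to define the region", call. = FALSE)
    region <- c(thr - region_halfwidth, thr + region_halfwidth)
  }
  minima <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      v <- sample(values, replace = TRUE)
      de <- try(estimate_density(v), silent = TRUE)
      if (inherits(de, "try-error")) return(NA_real_)
      # same guarded minimum definition as the full data: the split must
      # reproduce in the replicate, at a location inside the region
      thr_b <- find_global_minimum(de)
      if (is.null(thr_b) || thr_b < region[1] || thr_b > region[2]) {
        return(NA_real_)
      }
      thr_b
    }, numeric(1))
  })
  found <- minima[!is.na(minima)]
  structure(list(
    B = B, minima = found,
    detection_fraction = length(found) / B,
    p5 = if (length(found)) unname(quantile(found, 0.05, type = 7)) else NA_real_,
    p95 = if (length(found)) unname(quantile(found, 0.95, type = 7)) else NA_real_,
    region = region), class = "bootstrap_stability")
}

#' Assign protection classes from a threshold
#'
#' Protected (positive class) means pathogen colonization strictly below the
#' threshold; values equal to or above it are non-protected.
#'
#' @param values Named or unnamed numeric vector (log10 scale).
#' @param threshold Finite numeric threshold.
#' @return List of class `bimodal_split`: `threshold`, `classes` (factor,
#'   levels `protected`, `non_protected`), `n_protected`, `n_non_protected`.
#' @export
assign_classes <- function(values, threshold) {
  stopifnot(is.finite(threshold))
  cls <- factor(ifelse(values < threshold, "protected", "non_protected"),
                levels = c("protected", "non_protected"))
  names(cls) <- names(values)
  structure(list(threshold = threshold, classes = cls,
                 n_protected = sum(cls == "protected", na.rm = TRUE),
                 n_non_protected = sum(cls == "non_protected", na.rm = TRUE)),
            class = "bimodal_split")
}

#' Sample thresholds for the minima-sensitivity analysis
#'
#' Draws `m` thresholds from the bootstrap minima restricted to their 5th-95th
#' percentile range (without replacement when enough distinct minima exist);
#' when fewer than `m` minima fall in the range, falls back to uniform draws
#' on the range.
#'
#' @param bs A [bootstrap_stability()] result.
#' @param m Number of thresholds.
#' @param seed Integer seed.
#' @return Numeric vector of length `m`, all within `[p5, p95]`.
#' @export
sample_sensitivity_thresholds <- function(bs, m = 10, seed = 1) {
  stopifnot(inherits(bs, "bootstrap_stability"))
  inside <- bs$minima[bs$minima >= bs$p5 & bs$minima <= bs$p95]
  withr_seed(seed, {
    if (length(inside) >= m) {
      sample(inside, m, replace = FALSE)
    } else if (length(unique(inside)) == 1 && length(inside) >= 1) {
      rep(inside[1], m)
    } else {
      runif(m, bs$p5, bs$p95)
    }
  })
}

#' Fill missing per-experiment thresholds from a reference set
#'
#' When an experiment's density curve has no interior minimum (weak
#' bimodality in that draw), its threshold can be borrowed from a reference
#' screen — typically the mean of the training experiments' thresholds for a
#' test set, mirroring the option of reusing the training threshold.
#'
#' @param thresholds Tibble `experiment`, `threshold` (possibly NA).
#' @param reference Tibble of the same shape with usable thresholds.
#' @return `thresholds` with NAs replaced by the mean reference threshold.
#' @export
fill_missing_thresholds <- function(thresholds, reference) {
  ref <- mean(reference$threshold, na.rm = TRUE)
  if (!is.finite(ref)) stop("no usable reference threshold", call. = FALSE)
  thresholds$threshold[is.na(thresholds$threshold)] <- ref
  thresholds
}

#' Per-experiment protection thresholds and classes for a screen
#'
#' Estimates the density of community-level (box-median) pathogen
#' colonization within each experiment, finds the minimum between the two
#' main modes, and classifies both box medians and individual plants of that
#' experiment against it.
#'
#' @param dataset A `screen_data` on the log10 scale.
#' @param level `"median"` (box medians feed the KDE) or `"individual"`.
#' @param pooled_fallback When an experiment's own curve has no usable
#'   minimum, fall back to the minimum of the pooled distribution over all
#'   experiments of this screen (larger sample, narrower bandwidth).
#' @return Tibble per experiment: `experiment`, `threshold`, plus list
#'   columns with the box and plant class assignments.
#' @export
screen_thresholds <- function(dataset, level = c("median", "individual"),
                              pooled_fallback = TRUE) {
  stopifnot(inherits(dataset, "screen_data"), dataset$scale == "log10")
  level <- match.arg(level)
  agg <- aggregate_by_box(dataset)
  agg <- agg[!(agg$treatment %in% dataset$controls), ]
  pl <- dataset$plants
  pl <- pl[!(pl$treatment %in% dataset$controls) & !pl$excluded &
             !is.na(pl$pathogen_cfu), ]
  val_for <- function(e) {
    if (level == "median") agg$median_pathogen[agg$experiment == e] else
      pl$pathogen_cfu[pl$experiment == e]
  }
  rows <- lapply(unique(agg$experiment), function(e) {
    thr <- find_global_minimum(estimate_density(val_for(e)))
    tibble::tibble(experiment = e,
                   threshold = if (is.null(thr)) NA_real_ else thr)
  })
  out <- dplyr::bind_rows(rows)
  if (pooled_fallback && anyNA(out$threshold) && nrow(out) > 1) {
    pooled_vals <- if (level == "median") agg$median_pathogen else
      pl$pathogen_cfu
    pooled <- find_global_minimum(estimate_density(pooled_vals))
    if (!is.null(pooled)) out$threshold[is.na(out$threshold)] <- pooled
  }
  out
}
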