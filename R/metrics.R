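#' Pielou evenness of an abundance vector
#'
#' `J = H' / ln(S)` with `H' = -sum(p_i ln p_i)` over the `S` strains with
#' positive abundance. Invariant to rescaling; `J = 1` iff all positive
#' abundances are equal. Undefined (NA) below two positive strains.
#'
#' @param abundances Nonnegative numeric vector (CFU/g or proportions).
#' @param fixed_richness Optional integer: use this richness in the
#'   denominator (e.g. the inoculated community size) instead of the number
#'   of strains detected above the floor.
#' @return Evenness in `[0, 1]`, or `NA_real_` when undefined.
#' @export
pielou_evenness <- function(abundances, fixed_richness = NULL) {
  x <- abundances[!is.na(abundances) & abundances > 0]
  s_pos <- length(x)
  if (s_pos < 2) return(NA_real_)
  s_denom <- fixed_richness %||% s_pos
  if (s_denom < 2) return(NA_real_)
  p <- x / sum(x)
  h <- -sum(p * log(p))
  h / log(s_denom)
}

#' Faith's phylogenetic diversity of a strain set
#'
#' Sum of branch lengths of the minimal unrooted subtree spanning the member
#' strains. Any root in the input tree is ignored (the tree is unrooted
#' before pruning), so the metric does not depend on an uncertain root
#' placement.
#'
#' @param tree An `ape::phylo` with strains as tips.
#' @param members Character vector of at least two strain ids.
#' @return Branch-length sum (same units as the tree).
#' @export
faith_pd <- function(tree, members) {
  stopifnot(inherits(tree, "phylo"))
  members <- unique(members)
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown)) stop("strains not in tree: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (length(members) < 2) stop("Faith PD needs at least two members", call. = FALSE)
  tr <- ape::unroot(tree)
  if (length(members) == length(tr$tip.label)) return(sum(tr$edge.length))
  sub <- ape::keep.tip(tr, members)
  sub <- ape::collapse.singles(sub)
  sum(sub$edge.length)
}

#' Abundance-weighted mean pairwise phylogenetic distance
#'
#' `sum_{i<j} w_i w_j d_ij / sum_{i<j} w_i w_j` over unordered strain pairs
#' (self-pairs excluded), with `w` the relative abundances and `d_ij` the
#' patristic distance. With uniform weights this is the plain mean pairwise
#' distance.
#'
#' @param tree An `ape::phylo`, or a symmetric distance matrix with strain
#'   dimnames.
#' @param abundances Named nonnegative vector (strain -> abundance).
#' @return Weighted mpd (branch-length units), or `NA_real_` when fewer than
#'   two strains have positive abundance.
#' @export
weighted_mpd <- function(tree, abundances) {
  w <- abundances[!is.na(abundances) & abundances > 0]
  if (length(w) < 2) return(NA_real_)
  d <- if (inherits(tree, "phylo")) stats::cophenetic(tree) else as.matrix(tree)
  unknown <- setdiff(names(w), rownames(d))
  if (length(unknown)) stop("strains not in tree: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  d <- d[names(w), names(w), drop = FALSE]
  w <- w / sum(w)
  ww <- outer(w, w)
  up <- upper.tri(d)
  sum(ww[up] * d[up]) / sum(ww[up])
}

#' Community-structure metrics for a screen
#'
#' In `inoculum` mode, metrics use presence only: Faith PD of each distinct
#' community composition. In `realized` mode, metrics use end-point
#' abundances per plant: Pielou evenness and abundance-weighted mpd of the
#' measured strain CFUs, with flags marking plants whose communities contain
#' below-detection or ambiguous entries (those are excluded by the
#' sensitivity analyses, not here).
#'
#' @param dataset A `screen_data` (linear scale for realized abundances).
#' @param tree An `ape::phylo` covering the pool.
#' @param mode `"realized"` (per plant) or `"inoculum"` (per community).
#' @param fixed_richness Passed to [pielou_evenness()].
#' @return `inoculum`: tibble `community_id`, `faith_pd`. `realized`: tibble
#'   `plant_id`, `community_id`, `evenness`, `weighted_mpd`, `n_detected`,
#'   `has_below_detection`, `has_ambiguous`.
#' @export
community_metrics <- function(dataset, tree, mode = c("realized", "inoculum"),
                              fixed_richness = NULL) {
  stopifnot(inherits(dataset, "screen_data"))
  mode <- match.arg(mode)
  if (mode == "inoculum") {
    comms <- split(dataset$communities$strain_id, dataset$communities$community_id)
    return(tibble::tibble(
      community_id = names(comms),
      faith_pd = unname(vapply(comms, function(m) {
        tryCatch(faith_pd(tree, m), error = function(e) NA_real_)
      }, numeric(1)))))
  }
  if (dataset$scale != "linear") {
    stop("realized metrics need linear-scale abundances", call. = FALSE)
  }
  dmat <- stats::cophenetic(tree)
  st <- split(dataset$strains, dataset$strains$plant_id)
  pl <- dataset$plants[dataset$plants$plant_id %in% names(st), ]
  rows <- lapply(pl$plant_id, function(pid) {
    s <- st[[pid]]
    ab <- setNames(s$cfu_per_g, s$strain_id)
    # an ambiguous pooled pair carries the pooled value on both rows; halve
    # for metric purposes when not yet partitioned
    if (!dataset$ambiguity_partitioned && any(s$flag == "ambiguous")) {
      amb <- !is.na(s$ambiguity_group)
      sizes <- stats::ave(rep(1, sum(amb)), s$ambiguity_group[amb], FUN = sum)
      ab[amb] <- ab[amb] / sizes
    }
    tibble::tibble(
      plant_id = pid,
      community_id = pl$community_id[match(pid, pl$plant_id)],
      evenness = pielou_evenness(ab, fixed_richness),
      weighted_mpd = tryCatch(weighted_mpd(dmat, ab),
                              error = function(e) NA_real_),
      n_detected = sum(s$flag == "detected"),
      has_below_detection = any(s$flag == "below_detection"),
      has_ambiguous = any(s$flag == "ambiguous"))
  })
  dplyr::bind_rows(rows)
}
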