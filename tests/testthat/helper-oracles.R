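# Independent brute-force oracles and tiny fixtures used across the suite.

# Faith PD by union of edges on all member-pair paths (node-path walk),
# independent of the pruning-based implementation.
oracle_faith_pd <- function(tree, members) {
  tree <- ape::unroot(tree)
  idx <- match(members, tree$tip.label)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- character(0)
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i < j) {
        path <- ape::nodepath(tree, idx[i], idx[j])
        for (s in seq_len(length(path) - 1)) {
          keys <- c(keys, edge_key(path[s], path[s + 1]))
        }
      }
    }
  }
  keys <- unique(keys)
  all_keys <- edge_key(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[all_keys %in% keys])
}

# Weighted mean pairwise distance by explicit double loop.
oracle_weighted_mpd <- function(dmat, ab) {
  ab <- ab[ab > 0]
  w <- ab / sum(ab)
  ids <- names(w)
  num <- 0; den <- 0
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        num <- num + w[i] * w[j] * dmat[ids[i], ids[j]]
        den <- den + w[i] * w[j]
      }
    }
  }
  unname(num / den)
}

# Exhaustive enumeration of all k-subsets for prevalence checks.
oracle_all_communities <- function(n, k) {
  utils::combn(sprintf("s%02d", seq_len(n)), k, simplify = FALSE)
}

# Minimal hand-built screen_data: two communities x two plants plus one
# axenic box, linear scale.
tiny_screen <- function() {
  communities <- tibble::tibble(
    community_id = rep(c("c1", "c2"), each = 3),
    strain_id = c("A", "B", "C", "B", "C", "D"))
  plants <- tibble::tibble(
    experiment = "exp1",
    box_id = c("b1", "b1", "b2", "b2", "b3", "b3"),
    treatment = c("c1", "c1", "c2", "c2", "axenic", "axenic"),
    community_id = c("c1", "c1", "c2", "c2", NA, NA),
    plant_id = paste0("p", 1:6),
    fresh_weight_mg = 40,
    pathogen_cfu = c(1e5, 1e6, 1e8, 1e9, 10^8.2, 10^8.4),
    excluded = FALSE, exclude_reason = NA_character_)
  strains <- tibble::tibble(
    plant_id = rep(paste0("p", 1:4), each = 3),
    strain_id = c("A", "B", "C", "A", "B", "C", "B", "C", "D", "B", "C", "D"),
    cfu_per_g = c(1e7, 2e7, 1e7, 6e7, 1e7, 3e7, 5e6, 5e6, 4e7, 1e7, 1e7, 2e7),
    flag = "detected", ambiguity_group = NA_character_)
  screen_data(plants, strains, communities, controls = c("axenic", "axenic-NI"))
}

# Fast generator configuration for stochastic property loops.
small_null_config <- function() {
  delta <- stats::setNames(numeric(35), sprintf("strain_%02d", 1:35))
  generator_config(
    strain_effects = delta,
    synergy_effects = tibble::tibble(strain_a = character(),
                                     strain_b = character(), gamma = numeric()),
    commensal_slope = 0, commensal_slope_sd = 0,
    evenness_effect = 0, evenness_effect_sd = 0,
    context_amplification = 0,
    n_train_communities = 30L, n_train_experiments = 1L,
    n_test_communities = 10L, plants_per_box = 2L,
    n_axenic_boxes = 2L, n_axenic_ni_boxes = 0L,
    include_controls = FALSE,
    ambiguous_pairs = tibble::tibble(strain_a = character(),
                                     strain_b = character()),
    detection_floor = 0)
}
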