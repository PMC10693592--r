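#' Screen design specification
#'
#' A screen draws `N` communities of fixed size `k` from a pool of `n`
#' strains, each community sampled without replacement. The design controls
#' the expected prevalence of every strain across the screen, the quantity
#' that sets the statistical power available to strain-level analyses.
#'
#' @param k Community size (strains per SynCom).
#' @param n Strain-pool size.
#' @param N Number of screened communities.
#' @return A `design_spec` object (list with `k`, `n`, `N`).
#' @export
#' @examples
#' design_spec(k = 5, n = 35, N = 136)
design_spec <- function(k, n, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(N) == 1)
  if (!is.finite(k) || !is.finite(n) || !is.finite(N) ||
      k != round(k) || n != round(n) || N != round(N)) {
    stop("k, n and N must be integers", call. = FALSE)
  }
  if (k < 1 || n < 1 || N < 1) stop("k, n and N must be positive", call. = FALSE)
  if (k > n) stop("community size k cannot exceed pool size n", call. = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), N = as.integer(N)),
            class = "design_spec")
}

#' Strain pool
#'
#' @param strain_ids Character vector of unique strain labels.
#' @return A `strain_pool` object.
#' @export
strain_pool <- function(strain_ids) {
  strain_ids <- as.character(strain_ids)
  if (anyDuplicated(strain_ids)) stop("strain labels must be unique", call. = FALSE)
  if (length(strain_ids) < 1) stop("empty strain pool", call. = FALSE)
  structure(list(strain_ids = strain_ids, size = length(strain_ids)),
            class = "strain_pool")
}

#' Default labelled pool of a given size
#' @param n Pool size.
#' @export
default_pool <- function(n = 35) strain_pool(sprintf("strain_%02d", seq_len(n)))

#' Expected prevalence of a strain across the screen
#'
#' For communities of size `k` drawn uniformly without replacement from `n`
#' strains, a given strain appears in a community with probability
#' `choose(n-1, k-1) / choose(n, k) = k/n`, so its expected count over `N`
#' screened communities is `(k/n) * N`.
#'
#' @param spec A [design_spec()].
#' @return Expected number of communities containing any given strain (real).
#' @export
#' @examples
#' expected_prevalence(design_spec(5, 35, 136)) # 19.43
expected_prevalence <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  (spec$k / spec$n) * spec$N
}

#' Expected prevalence as a function of pool size
#'
#' @param k Community size.
#' @param N Number of communities.
#' @param n_range Integer vector of pool sizes to evaluate (all `>= k`).
#' @return A tibble with columns `n` and `expected_prevalence`, one row per
#'   pool size; non-increasing in `n`.
#' @export
prevalence_curve <- function(k, N, n_range) {
  if (length(n_range) == 0) stop("empty pool-size range", call. = FALSE)
  if (any(n_range < k)) stop("all pool sizes must be >= k", call. = FALSE)
  tibble::tibble(
    n = as.integer(n_range),
    expected_prevalence = vapply(
      n_range, function(n) expected_prevalence(design_spec(k, n, N)), numeric(1))
  )
}

#' Assemble random fixed-size communities
#'
#' Each community is `k` strains sampled without replacement from the pool.
#' With `enforce_unique = TRUE` (default) duplicated compositions are
#' rejection-sampled away so that no two communities are identical, matching
#' a screen in which every composition is distinct.
#'
#' @param pool A [strain_pool()].
#' @param spec A [design_spec()] with `n` equal to the pool size.
#' @param seed Integer seed; identical seeds reproduce identical sets.
#' @param enforce_unique Reject duplicate compositions.
#' @param exclude Optional list of character vectors: compositions that must
#'   not appear (used to keep a test screen disjoint from training).
#' @return A `community_set`: list with `communities` (named list of character
#'   vectors), `spec`, `seed` and a long-format `membership` tibble
#'   (`community_id`, `strain_id`).
#' @export
assemble_communities <- function(pool, spec, seed, enforce_unique = TRUE,
                                 exclude = list()) {
  stopifnot(inherits(pool, "strain_pool"), inherits(spec, "design_spec"))
  if (pool$size != spec$n) stop("pool size does not match design n", call. = FALSE)
  capacity <- choose(spec$n, spec$k)
  if (enforce_unique && spec$N + length(exclude) > capacity) {
    stop("requested more unique communities than choose(n, k) allows",
         call. = FALSE)
  }
  key <- function(members) paste(sort(members), collapse = "|")
  seen <- new.env(parent = emptyenv())
  for (comp in exclude) assign(key(comp), TRUE, envir = seen)

  communities <- vector("list", spec$N)
  withr_seed(seed, {
    i <- 1L
    tries <- 0L
    while (i <= spec$N) {
      members <- sample(pool$strain_ids, spec$k, replace = FALSE)
      k_ <- key(members)
      if (!enforce_unique || !exists(k_, envir = seen, inherits = FALSE)) {
        assign(k_, TRUE, envir = seen)
        communities[[i]] <- sort(members)
        i <- i + 1L
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 1e6) stop("rejection sampling stalled", call. = FALSE)
      }
    }
  })
  names(communities) <- sprintf("community_%03d", seq_len(spec$N))
  structure(
    list(communities = communities, spec = spec, seed = as.integer(seed),
         membership = tibble::tibble(
           community_id = rep(names(communities), each = spec$k),
           strain_id = unlist(communities, use.names = FALSE))),
    class = "community_set")
}

#' Realized per-strain prevalence of an assembled set
#'
#' @param cs A `community_set` (or a membership tibble with columns
#'   `community_id`, `strain_id`).
#' @param pool Optional [strain_pool()]; strains absent from every community
#'   are reported with count 0.
#' @return Tibble `strain_id`, `prevalence` (community counts). Counts sum to
#'   `k * N`.
#' @export
realized_prevalence <- function(cs, pool = NULL) {
  membership <- if (inherits(cs, "community_set")) cs$membership else cs
  counts <- table(membership$strain_id)
  ids <- if (is.null(pool)) sort(names(counts)) else pool$strain_ids
  tibble::tibble(
    strain_id = ids,
    prevalence = as.integer(ifelse(ids %in% names(counts), counts[ids], 0L)))
}

#' Write / read a community set as long-format CSV
#' @param cs A `community_set` or membership tibble.
#' @param path File path.
#' @export
write_communities <- function(cs, path) {
  membership <- if (inherits(cs, "community_set")) cs$membership else cs
  utils::write.csv(membership, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_communities
#' @export
read_communities <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
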