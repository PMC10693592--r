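#' @keywords internal
"_PACKAGE"

#' @importFrom stats AIC aggregate coef dgamma dnorm density median na.omit
#'   predict quantile rbinom rgamma rnorm runif sd setNames var vcov rbeta
#' @importFrom utils head tail
NULL

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards so package functions never disturb user-level randomness.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Dirichlet draw by gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha)) # numeric underflow guard
  g / sum(g)
}

# Cohen's kappa from a 2x2 (or larger) confusion table: rows = truth,
# columns = prediction, identical level order.
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(0)
  (po - pe) / (1 - pe)
}

rmse <- function(truth, pred) sqrt(mean((truth - pred)^2))
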