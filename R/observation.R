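# Poisson observation model: likelihood, synthetic observations,
# posterior-predictive draws.

check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 3L || anyNA(mu) || any(mu <= 0)) {
    stop("mu must be three strictly positive Poisson rates (mu0, mu1, mu2)")
  }
  as.numeric(mu)
}

check_label_matrix <- function(L) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop("label matrix must be square")
  v <- L[upper.tri(L)]
  if (anyNA(v) || !all(v %in% 0:2)) stop("labels must be in {0, 1, 2}")
  if (!isTRUE(all.equal(L[upper.tri(L)], t(L)[upper.tri(L)]))) {
    stop("label matrix must be symmetric")
  }
  invisible(L)
}

check_observations <- function(X) {
  if (!is.matrix(X) || nrow(X) != ncol(X)) {
    stop("observation matrix must be square")
  }
  v <- X[upper.tri(X)]
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("observation counts must be nonnegative integers")
  }
  if (any(X[upper.tri(X)] != t(X)[upper.tri(X)])) {
    stop("observation matrix must be symmetric")
  }
  invisible(X)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG stream;
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Poisson log-likelihood of pairwise observations
#'
#' Log-probability of the count matrix `X` given interaction types `L` and
#' Poisson rates `mu`: each pair `i < j` contributes an independent Poisson
#' term with mean \eqn{\mu_{\ell_{ij}}}.
#'
#' @param X Symmetric matrix of nonnegative integer observation counts.
#' @param L Label matrix with entries in `{0, 1, 2}` (see [project_labels()]).
#' @param mu Numeric vector `(mu0, mu1, mu2)` of strictly positive rates.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(X, L, mu) {
  mu <- check_mu(mu)
  check_observations(X)
  check_label_matrix(L)
  if (nrow(X) != nrow(L)) stop("X and L must have the same dimension")
  ut <- upper.tri(X)
  sum(dpois(X[ut], mu[L[ut] + 1L], log = TRUE))
}

#' Draw synthetic pairwise observations
#'
#' Generates an observation matrix from the Poisson data model: each pair
#' `i < j` is drawn independently from Poisson(\eqn{\mu_{\ell_{ij}}}).
#'
#' @inheritParams log_likelihood
#' @param seed Optional integer seed; when given the caller's RNG state is
#'   left untouched.
#' @return A symmetric integer count matrix with zero diagonal.
#' @export
sample_observations <- function(L, mu, seed = NULL) {
  mu <- check_mu(mu)
  check_label_matrix(L)
  n <- nrow(L)
  with_seed(seed, {
    X <- matrix(0L, n, n)
    ut <- which(upper.tri(X))
    X[ut] <- rpois(length(ut), mu[L[ut] + 1L])
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    X
  })
}

#' Posterior-predictive observation draw
#'
#' Given one posterior sample (a structure with its rates), projects the
#' structure to labels and regenerates a synthetic observation matrix from the
#' data model. Repeated over a chain, such draws support posterior-predictive
#' checks (see [residual_sums()]).
#'
#' @param sample A list with elements `structure` (a [hypergraph()] or
#'   [categorical_graph()]) and `mu` (three rates), e.g. one element of a
#'   chain returned by [run_chain()].
#' @param seed Optional integer seed.
#' @return A symmetric integer count matrix.
#' @export
posterior_predictive_draw <- function(sample, seed = NULL) {
  sample_observations(project_labels(sample$structure), sample$mu, seed = seed)
}
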