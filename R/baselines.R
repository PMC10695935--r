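# Threshold baseline classifiers with optimal weighted-Poisson cut points.

#' Intersection of two weighted Poisson distributions
#'
#' The point where \eqn{\psi_1 \mathrm{Pois}(x; \lambda_1)} and
#' \eqn{\psi_2 \mathrm{Pois}(x; \lambda_2)} cross:
#' \deqn{z = \frac{\lambda_2 - \lambda_1 - \ln\psi_2 + \ln\psi_1}
#'   {\ln\lambda_2 - \ln\lambda_1}.}
#' Thresholding at `z` minimizes the expected number of misclassifications
#' between the two components in the large-`n` limit.
#'
#' @param lambda1,lambda2 Poisson means, `0 < lambda1 < lambda2`.
#' @param psi1,psi2 Component weights in (0, 1); only their ratio matters.
#' @return The crossing point (a real number).
#' @export
poisson_intersection <- function(lambda1, psi1, lambda2, psi2) {
  stopifnot(lambda1 > 0, lambda2 > 0, psi1 > 0, psi1 < 1, psi2 > 0, psi2 < 1)
  if (lambda1 == lambda2) stop("lambda1 and lambda2 must differ")
  (lambda2 - lambda1 - log(psi2) + log(psi1)) / (log(lambda2) - log(lambda1))
}

#' Optimal classification thresholds for the three interaction types
#'
#' Cut points on observed counts separating type 0 from type 1 and type 1
#' from type 2, each the intersection of the adjacent weighted Poisson
#' components. Class weights are the marginal type probabilities -- in the
#' oracle setting, the proportions of each type in the ground-truth structure.
#'
#' @param mu Ordered rates `mu0 < mu1 < mu2`.
#' @param class_priors Probabilities of types 0..2 (positive; normalized
#'   internally).
#' @return A list with cut points `t1` and `t2`.
#' @export
optimal_thresholds <- function(mu, class_priors) {
  mu <- check_mu(mu)
  if (!(mu[1] < mu[2] && mu[2] < mu[3])) {
    stop("thresholds require mu0 < mu1 < mu2")
  }
  w <- as.numeric(class_priors)
  if (length(w) != 3L || any(w <= 0)) stop("class priors must be positive")
  w <- w / sum(w)
  list(
    t1 = poisson_intersection(mu[1], w[1], mu[2], w[2]),
    t2 = poisson_intersection(mu[2], w[2], mu[3], w[3])
  )
}

#' Threshold classification of pairwise counts
#'
#' The "Threshold x2" baseline: a pair is labelled strong (type 2) if
#' `x >= t2`, else weak (type 1) if `x >= t1`, else non-interacting.
#'
#' @param X Observation count matrix.
#' @param thresholds A list with `t1` and `t2` (see [optimal_thresholds()]),
#'   or two numbers.
#' @return A label matrix with entries in `{0, 1, 2}`.
#' @export
threshold_classify <- function(X, thresholds) {
  check_observations(X)
  t1 <- as.numeric(thresholds[["t1"]])
  t2 <- as.numeric(thresholds[["t2"]])
  L <- matrix(0L, nrow(X), ncol(X))
  L[X >= t1] <- 1L
  L[X >= t2] <- 2L
  diag(L) <- 0L
  L
}

#' Class priors from a posterior chain
#'
#' When no ground truth is available, the threshold baseline needs class
#' weights; this helper estimates them as the posterior-mean proportions of
#' each interaction type over the chain's projected labels.
#'
#' @param chain A `hyperchain` from [run_chain()].
#' @return Probabilities of types 0..2.
#' @export
class_priors_from_chain <- function(chain) {
  check_chain(chain)
  cnt <- label_count_array(chain)
  p <- colSums(cnt) / sum(cnt)
  names(p) <- 0:2
  p
}
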