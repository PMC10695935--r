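# Evaluation statistics: confusion matrix, relative reconstruction error,
# predicted-type proportions, label entropy, projected-triangle fraction and
# posterior-predictive residual sums.

#' Confusion matrix of interaction types
#'
#' Counts, over all pairs `i < j`, how often a pair of true type `r` was
#' predicted as type `s`. A perfect reconstruction gives a diagonal matrix
#' with trace `choose(n, 2)`.
#'
#' @param true_L,pred_L Label matrices of equal dimension.
#' @return A 3x3 integer matrix with rows = true type 0..2 and columns =
#'   predicted type 0..2.
#' @export
confusion_matrix <- function(true_L, pred_L) {
  check_label_matrix(true_L)
  check_label_matrix(pred_L)
  if (nrow(true_L) != nrow(pred_L)) {
    stop("label matrices must have the same dimension")
  }
  ut <- upper.tri(true_L)
  C <- table(factor(true_L[ut], levels = 0:2),
             factor(pred_L[ut], levels = 0:2))
  C <- matrix(as.integer(C), 3L, 3L,
              dimnames = list(true = 0:2, predicted = 0:2))
  C
}

#' Relative reconstruction error
#'
#' Fraction of true interacting pairs (type 1 or 2) whose type was
#' misclassified:
#' \deqn{\epsilon = \frac{c_{10} + c_{12} + c_{20} + c_{21}}
#'   {c_{10} + c_{11} + c_{12} + c_{20} + c_{21} + c_{22}}.}
#' Undefined (returns `NA`) when the ground truth has no interacting pairs.
#'
#' @param C A 3x3 confusion matrix from [confusion_matrix()].
#' @return The error in `[0, 1]`, or `NA_real_` if undefined.
#' @export
reconstruction_error <- function(C) {
  stopifnot(is.matrix(C), all(dim(C) == 3L))
  denom <- sum(C[2:3, ])
  if (denom == 0) return(NA_real_)
  (C[2, 1] + C[2, 3] + C[3, 1] + C[3, 2]) / denom
}

#' Proportions of pairs predicted as each type
#'
#' @param C A 3x3 confusion matrix.
#' @return Numeric vector `(rho0, rho1, rho2)` summing to 1.
#' @export
type_proportions <- function(C) {
  stopifnot(is.matrix(C), all(dim(C) == 3L))
  colSums(C) / sum(C)
}

#' Entropy of the predicted label distribution
#'
#' \deqn{S = -\sum_k \rho_k \log_3 \rho_k,} with \eqn{0 \log 0 = 0}. Base 3
#' makes `S = 1` when the three types are uniformly represented and `S = 0`
#' when a single type exists.
#'
#' @param rho Proportions of the three types (must sum to 1).
#' @return Entropy in `[0, 1]`.
#' @export
label_entropy <- function(rho) {
  rho <- as.numeric(rho)
  stopifnot(length(rho) == 3L, all(rho >= 0),
            isTRUE(all.equal(sum(rho), 1)))
  nz <- rho > 0
  -sum(rho[nz] * log(rho[nz], base = 3)) + 0  # + 0 avoids returning -0
}

#' Fraction of 2-edges closing a projected triangle
#'
#' The proportion \eqn{E_\Delta} of 2-edges `(i, j)` for which some third
#' vertex `k` has both `(i, k)` and `(j, k)` present in the projected
#' interaction graph \eqn{\Delta \cup E}. Values near 0 indicate a best-case
#' hypergraph (neighborhoods are maximally informative about 3-edges), values
#' near 1 a worst-case one. Undefined (`NA`) when the hypergraph has no
#' 2-edges.
#'
#' @param H A [hypergraph()].
#' @return A value in `[0, 1]`, or `NA_real_` if `H` has no 2-edges.
#' @export
triangle_fraction <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  h1 <- nrow(H$edges)
  if (h1 == 0L) return(NA_real_)
  M <- matrix(FALSE, H$n, H$n)
  M <- sym_assign(M, H$edges, TRUE)
  M <- sym_assign(M, covered_pairs(H), TRUE)
  closes <- vapply(seq_len(h1), function(r) {
    i <- H$edges[r, 1]
    j <- H$edges[r, 2]
    any(M[i, ] & M[j, ])
  }, logical(1))
  mean(closes)
}

#' Posterior-predictive residual sums
#'
#' For `n_draws` posterior samples (cycling through the chain), draws a
#' predictive observation matrix from the sample's structure and rates and
#' accumulates, per interaction type `k` of that sample's projected labels,
#' \deqn{R_k = \sum_{i<j} (x_{ij} - \tilde{x}_{ij}) \delta_{k, \ell_{ij}}.}
#' Residuals near zero for every type indicate that the fitted model
#' reproduces the data on average -- a posterior-predictive check.
#'
#' @param X The observed count matrix.
#' @param chain A `hyperchain` from [run_chain()].
#' @param n_draws Number of predictive matrices (default 200).
#' @param seed Optional integer seed.
#' @return A list with `mean` and `sum`: per-type residuals averaged, and
#'   totalled, over the draws (named `R0`, `R1`, `R2`).
#' @export
residual_sums <- function(X, chain, n_draws = 200L, seed = NULL) {
  check_chain(chain)
  check_observations(X)
  if (nrow(X) != chain$n) stop("X dimension does not match the chain")
  ut <- upper.tri(X)
  with_seed(seed, {
    acc <- matrix(0, n_draws, 3L)
    N <- length(chain$samples)
    for (d in seq_len(n_draws)) {
      s <- chain$samples[[(d - 1L) %% N + 1L]]
      L <- project_labels(s$structure)
      Xt <- sample_observations(L, s$mu)
      diffs <- X[ut] - Xt[ut]
      lab <- L[ut]
      for (k in 0:2) acc[d, k + 1L] <- sum(diffs[lab == k])
    }
    res_mean <- colMeans(acc)
    res_sum <- colSums(acc)
    names(res_mean) <- names(res_sum) <- c("R0", "R1", "R2")
    list(mean = res_mean, sum = res_sum)
  })
}
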