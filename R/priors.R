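# Structure priors, conjugate hyperpriors on (mu, phi), and prior samplers.

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop(what, " must lie strictly inside (0, 1)")
  }
  as.numeric(p)
}

#' Hyperprior specification for rates and structure probabilities
#'
#' Conjugate hyperpriors: independent gamma priors on the Poisson rates
#' `mu0, mu1, mu2` and beta priors on the two structure probabilities
#' (`q`, `p` for the hypergraph model; `q1`, `q2` for the categorical-edges
#' model). The defaults -- gamma(shape 1, rate 0.1), i.e. mean 10, and
#' beta(1, 1) -- are weakly informative.
#'
#' @param mu_shape,mu_rate Gamma shape and rate for each of the three rates
#'   (recycled to length 3).
#' @param beta_a,beta_b Beta parameters for each of the two structure
#'   probabilities (recycled to length 2).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_shape = 1, mu_rate = 0.1, beta_a = 1, beta_b = 1) {
  spec <- list(
    mu_shape = rep_len(as.numeric(mu_shape), 3L),
    mu_rate = rep_len(as.numeric(mu_rate), 3L),
    beta_a = rep_len(as.numeric(beta_a), 2L),
    beta_b = rep_len(as.numeric(beta_b), 2L)
  )
  if (any(unlist(spec) <= 0) || anyNA(unlist(spec))) {
    stop("all hyper-hyperparameters must be strictly positive")
  }
  structure(spec, class = "prior_spec")
}

#' Log prior probability of a hypergraph
#'
#' Bernoulli hyperedge prior: every 2-edge exists independently with
#' probability `q` and every 3-edge with probability `p`, so
#' \deqn{\log P(H) = h_1 \log q + (\binom{n}{2} - h_1)\log(1-q)
#'   + h_2 \log p + (\binom{n}{3} - h_2)\log(1-p).}
#'
#' @param H A [hypergraph()].
#' @param phi Named list or vector with elements `q` (2-edge probability) and
#'   `p` (3-edge probability), both in (0, 1).
#' @return The log prior probability.
#' @export
log_prior_hypergraph <- function(H, phi) {
  stopifnot(inherits(H, "hypergraph"))
  q <- check_prob(phi[["q"]], "q")
  p <- check_prob(phi[["p"]], "p")
  h1 <- nrow(H$edges)
  h2 <- nrow(H$triples)
  h1 * log(q) + (choose(H$n, 2) - h1) * log1p(-q) +
    h2 * log(p) + (choose(H$n, 3) - h2) * log1p(-p)
}

#' Log prior probability of a categorical-edges graph
#'
#' Two-step generative prior: strong edges placed independently with
#' probability `q2`, then weak edges placed independently with probability
#' `q1` among the remaining unconnected pairs:
#' \deqn{\log P(G) = m_1 \log q_1 + (\binom{n}{2} - m_1 - m_2)\log(1-q_1)
#'   + m_2 \log q_2 + (\binom{n}{2} - m_2)\log(1-q_2).}
#'
#' @param G A [categorical_graph()].
#' @param phi Named list or vector with weak-edge probability `q1` and
#'   strong-edge probability `q2`.
#' @return The log prior probability.
#' @export
log_prior_graph <- function(G, phi) {
  stopifnot(inherits(G, "categorical_graph"))
  if (length(intersect(pair_keys(G$weak, G$n), pair_keys(G$strong, G$n))) > 0L) {
    stop("weak and strong edge sets overlap")
  }
  q1 <- check_prob(phi[["q1"]], "q1")
  q2 <- check_prob(phi[["q2"]], "q2")
  m1 <- nrow(G$weak)
  m2 <- nrow(G$strong)
  npairs <- choose(G$n, 2)
  m1 * log(q1) + (npairs - m1 - m2) * log1p(-q1) +
    m2 * log(q2) + (npairs - m2) * log1p(-q2)
}

#' Log density of the hyperprior on rates and structure probabilities
#'
#' Sum of gamma log-densities on `mu` and beta log-densities on the two
#' probabilities in `phi`, under a [prior_spec()].
#'
#' @param mu Three positive Poisson rates.
#' @param phi Two structure probabilities, in the order (`q`, `p`) for the
#'   hypergraph model or (`q1`, `q2`) for the categorical-edges model.
#' @param spec A [prior_spec()].
#' @return The log hyperprior density.
#' @export
log_hyperprior <- function(mu, phi, spec = prior_spec()) {
  mu <- check_mu(mu)
  phi <- as.numeric(phi)
  if (length(phi) != 2L || any(phi <= 0) || any(phi >= 1)) {
    stop("phi must be two probabilities in (0, 1)")
  }
  sum(dgamma(mu, shape = spec$mu_shape, rate = spec$mu_rate, log = TRUE)) +
    sum(dbeta(phi, spec$beta_a, spec$beta_b, log = TRUE))
}

#' Sample a hypergraph from its Bernoulli prior
#'
#' @param n Number of vertices (`n >= 2`; 3-edges require `n >= 3`).
#' @param phi List/vector with 2-edge probability `q` and 3-edge probability
#'   `p`.
#' @param seed Optional integer seed.
#' @return A [hypergraph()].
#' @export
sample_hypergraph_prior <- function(n, phi, seed = NULL) {
  q <- as.numeric(phi[["q"]])
  p <- as.numeric(phi[["p"]])
  stopifnot(q >= 0, q <= 1, p >= 0, p <= 1, n >= 2)
  with_seed(seed, {
    P <- all_pairs(n)
    Tm <- all_triples(n)
    hypergraph(
      n,
      edges = P[runif(nrow(P)) < q, , drop = FALSE],
      triples = Tm[runif(nrow(Tm)) < p, , drop = FALSE]
    )
  })
}

#' Sample a categorical-edges graph from its two-step prior
#'
#' Strong edges are placed first, independently with probability `q2`; weak
#' edges are then placed independently with probability `q1` among the pairs
#' left unconnected, so the two sets never overlap.
#'
#' @param n Number of vertices.
#' @param phi List/vector with weak-edge probability `q1` and strong-edge
#'   probability `q2`.
#' @param seed Optional integer seed.
#' @return A [categorical_graph()].
#' @export
sample_graph_prior <- function(n, phi, seed = NULL) {
  q1 <- as.numeric(phi[["q1"]])
  q2 <- as.numeric(phi[["q2"]])
  stopifnot(q1 >= 0, q1 <= 1, q2 >= 0, q2 <= 1, n >= 2)
  with_seed(seed, {
    P <- all_pairs(n)
    strong <- runif(nrow(P)) < q2
    weak <- !strong & (runif(nrow(P)) < q1)
    categorical_graph(
      n,
      weak = P[weak, , drop = FALSE],
      strong = P[strong, , drop = FALSE]
    )
  })
}
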