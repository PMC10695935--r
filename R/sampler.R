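# Metropolis-within-Gibbs samplers for the two structural models.
#
# Each sweep performs a block of single-hyperedge flip proposals at fixed
# (mu, phi), then conjugate Gibbs draws of mu (truncated gamma, enforcing the
# identifiability ordering) and phi (beta). Proposals are symmetric, so the
# Metropolis ratio is a posterior ratio evaluated over the affected pairs.

#' Sampler configuration
#'
#' @param model `"hypergraph"` or `"graph"` (categorical edges).
#' @param n_samples Number of retained posterior samples (default 500).
#' @param burn_in Number of discarded initial sweeps.
#' @param thinning Keep one sample every `thinning` sweeps.
#' @param proposals_per_sweep Structure proposals per sweep. Default
#'   `choose(n,2) + choose(n,3)` for the hypergraph model, capped at
#'   `20 * choose(n,2)` when `n > 40` (the 3-edge space is then subsampled
#'   uniformly); `choose(n,2)` for the graph model.
#' @param update_mu,update_phi Set to `FALSE` to hold the rates or structure
#'   probabilities fixed at their initial values (useful for validating the
#'   structure moves against exhaustive enumeration).
#' @param seed Integer seed making the chain fully reproducible.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(model = c("hypergraph", "graph"),
                           n_samples = 500L, burn_in = 2000L, thinning = 10L,
                           proposals_per_sweep = NULL,
                           update_mu = TRUE, update_phi = TRUE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_samples >= 1L, burn_in >= 0L, thinning >= 1L)
  structure(
    list(
      model = model, n_samples = as.integer(n_samples),
      burn_in = as.integer(burn_in), thinning = as.integer(thinning),
      proposals_per_sweep = proposals_per_sweep,
      update_mu = isTRUE(update_mu), update_phi = isTRUE(update_phi),
      seed = seed
    ),
    class = "sampler_config"
  )
}

default_proposals <- function(n, model) {
  if (model == "graph") return(as.integer(choose(n, 2)))
  total <- choose(n, 2) + choose(n, 3)
  if (n > 40L) total <- min(total, 20 * choose(n, 2))
  as.integer(total)
}

# ---- initialization ---------------------------------------------------------

# EM for a 1-D 3-component Poisson mixture; returns sorted rates, weights and
# hard assignments. Used only to initialize the chain. Several data-driven
# starting points are tried and the best final log-likelihood wins; sparse
# count data easily traps a single EM run in a local optimum that splits the
# zero mass instead of separating the two interacting components.
poisson_mixture_em_once <- function(x, lambda, max_iter = 200L, tol = 1e-8) {
  k <- length(lambda)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(k),
                 function(j) log(w[j]) + dpois(x, lambda[j], log = TRUE),
                 numeric(length(x)))
    mx <- apply(lp, 1L, max)
    post <- exp(lp - mx)
    rs <- rowSums(post)
    ll <- sum(mx + log(rs))
    post <- post / rs
    w <- colMeans(post)
    lambda <- pmax(colSums(post * x) / pmax(colSums(post), 1e-12), 1e-6)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  if (!is.finite(ll) || any(w < 1e-6) || any(!is.finite(lambda))) return(NULL)
  ord <- order(lambda)
  if (min(diff(lambda[ord])) < 1e-9) return(NULL)
  list(lambda = lambda[ord], weight = w[ord],
       assign = max.col(post[, ord, drop = FALSE], ties.method = "first") - 1L,
       loglik = ll)
}

poisson_mixture_em <- function(x, max_iter = 200L) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(NULL)
  pos <- x[x > 0]
  qn <- function(v, p) as.numeric(quantile(v, p, names = FALSE))
  starts <- list(
    pmax(c(qn(x, 0.5), qn(x, 0.9), qn(x, 0.99)) + c(1e-3, 0.101, 0.201),
         1e-3),
    mean(x) * c(0.1, 1, 3) + c(1e-3, 0.01, 0.02)
  )
  if (length(pos) >= 2L) {
    starts <- c(starts, list(
      # zeros vs a split of the positive counts: the typical sparse regime
      pmax(c(1e-3, qn(pos, 0.25), qn(pos, 0.75)) + c(0, 0.01, 0.02), 1e-3),
      pmax(c(mean(x[x <= qn(x, 0.5)]), max(pos) / 2, max(pos)) +
             c(1e-3, 0.01, 0.02), 1e-3)
    ))
  }
  fits <- lapply(starts, function(l0) {
    if (min(diff(sort(l0))) < 1e-9) return(NULL)
    poisson_mixture_em_once(x, sort(l0), max_iter = max_iter)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(NULL)
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

# Greedy local posterior selection of candidate 3-edges at initialization.
# Starting from no 3-edges, candidates (triangles of the interacting graph)
# are visited in decreasing order of standalone gain -- the log-posterior
# difference between "3-edge present, its 2-edges pruned" and "no 3-edge,
# pairs fall back on their 2-edges", at the EM rate estimates -- and added
# when their gain over still-uncovered pairs is positive. Visiting strong
# candidates first means a spurious triangle that merely re-covers their
# pairs never enters: by then only its weakest pair still counts.
prune_candidate_triples <- function(tri, X, mu, n) {
  if (nrow(tri) == 0L) return(tri)
  npairs <- choose(n, 2)
  q_hat <- min(max(sum(X > 0) / 2, 1) / npairs, 0.5)
  p_hat <- min(max(nrow(tri), 1) / max(choose(n, 3), 1), 0.5)
  lq_odds <- log(q_hat / (1 - q_hat))
  lp_odds <- log(p_hat / (1 - p_hat))
  tri_pairs <- function(t) rbind(t[c(1, 2)], t[c(1, 3)], t[c(2, 3)])
  pair_gain <- function(x) {
    dpois(x, mu[3], log = TRUE) -
      pmax(dpois(x, mu[2], log = TRUE) + lq_odds, dpois(x, mu[1], log = TRUE))
  }
  standalone <- vapply(seq_len(nrow(tri)), function(r) {
    lp_odds + sum(pair_gain(X[tri_pairs(tri[r, ])]))
  }, numeric(1))
  cov <- matrix(FALSE, n, n)
  keep <- rep(FALSE, nrow(tri))
  for (r in order(standalone, decreasing = TRUE)) {
    idx <- tri_pairs(tri[r, ])
    open <- !cov[idx]
    gain <- lp_odds +
      if (any(open)) sum(pair_gain(X[idx[open, , drop = FALSE]])) else 0
    if (gain > 0) {
      keep[r] <- TRUE
      cov[idx] <- TRUE
      cov[idx[, 2:1]] <- TRUE
    }
  }
  tri[keep, , drop = FALSE]
}

# Triangles of an adjacency (logical) matrix, as a 3-column matrix i<j<k.
adjacency_triangles <- function(A) {
  n <- nrow(A)
  out <- list()
  for (i in seq_len(n)) {
    nb <- which(A[i, ] & seq_len(n) > i)
    if (length(nb) < 2L) next
    for (j in nb) {
      ks <- nb[nb > j & A[j, nb]]
      if (length(ks)) out[[length(out) + 1L]] <- cbind(i, j, ks)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

#' Heuristic initialization of a chain
#'
#' Fits a one-dimensional three-component Poisson-mixture EM to the observed
#' counts (falling back to an empirical quantile split when EM degenerates),
#' sets the rates to the sorted component means, and classifies pairs at the
#' unweighted pmf crossings of adjacent components. The graph model starts
#' from the structure matching these labels. The hypergraph model starts
#' from all interacting pairs as 2-edges, with 3-edges seeded from the
#' triangles of the interacting graph that pass a greedy local posterior
#' test at the initial estimates; the 2-edge backbone keeps the weak class
#' populated while the seeded triangles anchor the strong class.
#' Structure probabilities start at empirical proportions.
#'
#' @param X Symmetric observation count matrix.
#' @param model `"hypergraph"` or `"graph"`.
#' @param spec A [prior_spec()]; supplies fallback rate values (prior means)
#'   when `X` is degenerate (all counts equal).
#' @return A list with `structure`, `mu` and `phi`.
#' @export
init_heuristic <- function(X, model = c("hypergraph", "graph"),
                           spec = prior_spec()) {
  model <- match.arg(model)
  check_observations(X)
  n <- nrow(X)
  pairs <- all_pairs(n)
  x <- X[pairs]
  em <- poisson_mixture_em(x)
  if (is.null(em)) {
    if (stats::sd(x) == 0 || all(x == x[1])) {
      # degenerate data: prior-mean rates (made strictly increasing), empty
      # structure
      mu <- sort(spec$mu_shape / spec$mu_rate) + c(0, 1e-3, 2e-3)
      lab <- rep(0L, length(x))
    } else {
      # quantile split: bottom ~90% type 0, next ~7% type 1, top ~3% type 2
      t1 <- quantile(x, 0.90)
      t2 <- quantile(x, 0.97)
      lab <- ifelse(x > t2, 2L, ifelse(x > t1, 1L, 0L))
      mu <- vapply(0:2, function(k) {
        if (any(lab == k)) mean(x[lab == k]) else NA_real_
      }, numeric(1))
      mu[is.na(mu)] <- (spec$mu_shape / spec$mu_rate)[is.na(mu)]
      mu <- pmax(mu, 1e-6)
      mu <- sort(mu) + c(0, 1e-3, 2e-3) * max(mu, 1)
    }
  } else {
    mu <- pmax(em$lambda, 1e-6)
    # hard assignment by the unweighted pmf crossings of the fitted
    # components: the weighted boundary starves the rarest class when two
    # components overlap, which would seed the chain with no 3-edges at all
    t1 <- poisson_intersection(mu[1], 0.5, mu[2], 0.5)
    t2 <- poisson_intersection(mu[2], 0.5, mu[3], 0.5)
    lab <- ifelse(x >= max(t2, t1), 2L, ifelse(x >= t1, 1L, 0L))
  }
  clamp01 <- function(p, slots) {
    pmin(pmax(p, 1 / (slots + 2)), 1 - 1 / (slots + 2))
  }
  npairs <- nrow(pairs)
  if (model == "hypergraph") {
    # Start from all interacting pairs as 2-edges, with 3-edges seeded from
    # the triangles of the interacting graph that pass a greedy local
    # posterior test at the initial parameter estimates. Seeding matters in
    # both directions: a missing 3-edge is slow to nucleate against
    # already-placed 2-edges, while a wrongly promoted one becomes
    # unremovable once the hidden 2-edges beneath it are pruned (their
    # removal is prior-favored and likelihood-neutral, so it happens first).
    A1 <- matrix(FALSE, n, n)
    A1 <- sym_assign(A1, pairs[lab >= 1L, , drop = FALSE], TRUE)
    tri <- prune_candidate_triples(adjacency_triangles(A1), X, mu, n)
    H <- hypergraph(n, edges = pairs[lab >= 1L, , drop = FALSE],
                    triples = tri)
    phi <- c(q = clamp01(nrow(H$edges) / npairs, npairs),
             p = clamp01(nrow(H$triples) / max(choose(n, 3), 1), choose(n, 3)))
    list(structure = H, mu = mu, phi = phi)
  } else {
    G <- categorical_graph(n,
                           weak = pairs[lab == 1L, , drop = FALSE],
                           strong = pairs[lab == 2L, , drop = FALSE])
    phi <- c(q1 = clamp01(nrow(G$weak) / npairs, npairs),
             q2 = clamp01(nrow(G$strong) / npairs, npairs))
    list(structure = G, mu = mu, phi = phi)
  }
}

# ---- individual updates -----------------------------------------------------

label_sufficient_stats <- function(X, L) {
  ut <- upper.tri(X)
  lab <- L[ut]
  x <- X[ut]
  list(
    sumx = vapply(0:2, function(k) sum(x[lab == k]), numeric(1)),
    cnt = vapply(0:2, function(k) sum(lab == k), numeric(1))
  )
}

#' Conjugate Gibbs draw of the Poisson rates
#'
#' With the labels held fixed, each rate has a gamma full conditional
#' (prior shape + type-k count sum, prior rate + number of type-k pairs),
#' truncated so the model's ordering constraint holds: `mu0 < mu1` and
#' `mu0 < mu2` for the hypergraph model, `mu0 < mu1 < mu2` for the graph
#' model. Sampling uses the inverse-CDF method. A type with no pairs is drawn
#' from its (truncated) prior.
#'
#' @param X Observation matrix.
#' @param L Label matrix (see [project_labels()]).
#' @param spec A [prior_spec()].
#' @param model Constraint set: `"hypergraph"`, `"graph"`, or `"none"`.
#' @param mu_current Optional current rates; when supplied, truncation bounds
#'   come from them (the proper Gibbs full conditional used inside
#'   [run_chain()]). Otherwise bounds are applied sequentially to the values
#'   drawn so far.
#' @param seed Optional integer seed.
#' @return Numeric vector `(mu0, mu1, mu2)` respecting the constraints.
#' @export
gibbs_update_mu <- function(X, L, spec = prior_spec(),
                            model = c("hypergraph", "graph", "none"),
                            mu_current = NULL, seed = NULL) {
  model <- match.arg(model)
  check_observations(X)
  check_label_matrix(L)
  st <- label_sufficient_stats(X, L)
  constraint <- match(model, c("none", "hypergraph", "graph")) - 1L
  with_seed(seed, {
    gibbs_mu_cpp(st$sumx, st$cnt, spec$mu_shape, spec$mu_rate, constraint,
                 if (is.null(mu_current)) numeric(3) else check_mu(mu_current),
                 !is.null(mu_current))
  })
}

#' Conjugate Gibbs draw of the structure probabilities
#'
#' Beta-conjugate draws given the structure: for a hypergraph,
#' `q ~ Beta(a + h1, b + C(n,2) - h1)` and `p ~ Beta(a + h2, b + C(n,3) - h2)`;
#' for a categorical-edges graph, `q1 ~ Beta(a + m1, b + C(n,2) - m1 - m2)`
#' and `q2 ~ Beta(a + m2, b + C(n,2) - m2)`.
#'
#' @param structure A [hypergraph()] or [categorical_graph()].
#' @param spec A [prior_spec()].
#' @param seed Optional integer seed.
#' @return Named vector: `(q, p)` or `(q1, q2)`.
#' @export
gibbs_update_phi <- function(structure, spec = prior_spec(), seed = NULL) {
  with_seed(seed, {
    if (inherits(structure, "hypergraph")) {
      n <- structure$n
      h1 <- nrow(structure$edges)
      h2 <- nrow(structure$triples)
      c(q = rbeta(1, spec$beta_a[1] + h1, spec$beta_b[1] + choose(n, 2) - h1),
        p = rbeta(1, spec$beta_a[2] + h2, spec$beta_b[2] + choose(n, 3) - h2))
    } else if (inherits(structure, "categorical_graph")) {
      n <- structure$n
      m1 <- nrow(structure$weak)
      m2 <- nrow(structure$strong)
      np <- choose(n, 2)
      c(q1 = rbeta(1, spec$beta_a[1] + m1, spec$beta_b[1] + np - m1 - m2),
        q2 = rbeta(1, spec$beta_a[2] + m2, spec$beta_b[2] + np - m2))
    } else {
      stop("structure must be a hypergraph or categorical_graph")
    }
  })
}

#' Metropolis update of the latent structure
#'
#' Performs a block of single-hyperedge flip proposals at fixed rates and
#' structure probabilities. For the hypergraph model, each proposal uniformly
#' chooses a pair-flip or a triple-flip and then a uniform candidate; for the
#' graph model, a uniform pair and a uniform different label. Proposals are
#' symmetric, so acceptance uses the posterior ratio, with likelihood terms
#' evaluated only over pairs whose label changes.
#'
#' @param structure Current [hypergraph()] or [categorical_graph()].
#' @param X Observation matrix.
#' @param mu Three Poisson rates (held fixed).
#' @param phi Structure probabilities (`q`, `p`) or (`q1`, `q2`), held fixed.
#' @param n_proposals Number of flip proposals.
#' @param seed Optional integer seed.
#' @return The updated structure.
#' @export
mh_update_structure <- function(structure, X, mu, phi, n_proposals,
                                seed = NULL) {
  check_observations(X)
  mu <- check_mu(mu)
  storage.mode(X) <- "integer"
  with_seed(seed, {
    if (inherits(structure, "hypergraph")) {
      q <- check_prob(phi[["q"]], "q")
      p <- check_prob(phi[["p"]], "p")
      res <- mh_structure_hyper_cpp(X, structure$edges, structure$triples,
                                    mu, q, p, as.integer(n_proposals))
      hypergraph(structure$n, edges = res$edges, triples = res$triples)
    } else if (inherits(structure, "categorical_graph")) {
      q1 <- check_prob(phi[["q1"]], "q1")
      q2 <- check_prob(phi[["q2"]], "q2")
      res <- mh_structure_graph_cpp(X, structure$weak, structure$strong,
                                    mu, q1, q2, as.integer(n_proposals))
      categorical_graph(structure$n, weak = res$weak, strong = res$strong)
    } else {
      stop("structure must be a hypergraph or categorical_graph")
    }
  })
}

# ---- full chain -------------------------------------------------------------

#' Run a Metropolis-within-Gibbs chain
#'
#' Alternates a block of structure flip proposals, a conjugate truncated-gamma
#' draw of the rates and a beta draw of the structure probabilities; discards
#' `burn_in` sweeps and then keeps every `thinning`-th state until `n_samples`
#' samples are retained. Each retained sample records the structure, `mu`,
#' `phi` and the log-posterior (up to the normalizing constant `P(X)`).
#'
#' @param X Symmetric observation count matrix.
#' @param config A [sampler_config()].
#' @param spec A [prior_spec()].
#' @param init Optional list with `structure`, `mu`, `phi`; defaults to
#'   [init_heuristic()].
#' @return An object of class `hyperchain`: a list with `model`, `samples`
#'   (each a list with `structure`, `mu`, `phi`, `log_posterior`, `sweep`)
#'   and the configuration used.
#' @examples
#' H <- hypergraph(5, edges = rbind(c(1, 2), c(4, 5)), triples = rbind(1:3))
#' X <- sample_observations(project_labels(H), c(0.05, 8, 15), seed = 1)
#' ch <- run_chain(X, sampler_config("hypergraph", n_samples = 50,
#'                                   burn_in = 50, thinning = 2, seed = 1))
#' map_estimate(ch)
#' @export
run_chain <- function(X, config, spec = prior_spec(), init = NULL) {
  stopifnot(inherits(config, "sampler_config"))
  check_observations(X)
  storage.mode(X) <- "integer"
  n <- nrow(X)
  if (config$model == "hypergraph" && n < 3L) {
    stop("the hypergraph model requires at least 3 vertices")
  }
  props <- config$proposals_per_sweep
  if (is.null(props)) props <- default_proposals(n, config$model)
  run <- function() {
    if (is.null(init)) init <- init_heuristic(X, config$model, spec)
    mu <- check_mu(init$mu)
    phi <- as.numeric(init$phi)
    raw <- if (config$model == "hypergraph") {
      run_chain_hyper_cpp(X, init$structure$edges, init$structure$triples,
                          mu, phi, unclass(spec), config$n_samples,
                          config$burn_in, config$thinning, as.integer(props),
                          config$update_mu, config$update_phi)
    } else {
      run_chain_graph_cpp(X, init$structure$weak, init$structure$strong,
                          mu, phi, unclass(spec), config$n_samples,
                          config$burn_in, config$thinning, as.integer(props),
                          config$update_mu, config$update_phi)
    }
    samples <- lapply(raw, function(s) {
      s$structure <- if (config$model == "hypergraph") {
        hypergraph(n, edges = s$edges, triples = s$triples)
      } else {
        categorical_graph(n, weak = s$weak, strong = s$strong)
      }
      s[c("structure", "mu", "phi", "log_posterior", "sweep")]
    })
    structure(
      list(model = config$model, samples = samples, config = config,
           prior = spec, n = n),
      class = "hyperchain"
    )
  }
  with_seed(config$seed, run())
}

#' @export
print.hyperchain <- function(x, ...) {
  lp <- vapply(x$samples, `[[`, numeric(1), "log_posterior")
  cat(sprintf(
    "Posterior chain (%s model): %d samples over %d vertices\n",
    x$model, length(x$samples), x$n
  ))
  cat(sprintf("  log-posterior: min %.2f, median %.2f, max %.2f\n",
              min(lp), median(lp), max(lp)))
  invisible(x)
}
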