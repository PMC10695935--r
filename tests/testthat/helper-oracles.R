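# Test helpers: exhaustive posterior enumeration on tiny instances, Monte
# Carlo standard errors, and hand-built chains.

# All 2^(C(n,2) + C(n,3)) hypergraphs on n vertices (n <= 4 in practice).
enumerate_hypergraphs <- function(n) {
  P <- hyperinfer:::all_pairs(n)
  Tm <- hyperinfer:::all_triples(n)
  ne <- nrow(P)
  nt <- nrow(Tm)
  out <- vector("list", 2^(ne + nt))
  idx <- 1L
  for (me in 0:(2^ne - 1)) {
    es <- P[bitwAnd(me, bitwShiftL(1L, seq_len(ne) - 1L)) > 0L, ,
            drop = FALSE]
    for (mt in 0:(2^nt - 1)) {
      ts <- Tm[bitwAnd(mt, bitwShiftL(1L, seq_len(nt) - 1L)) > 0L, ,
               drop = FALSE]
      out[[idx]] <- hypergraph(n, edges = es, triples = ts)
      idx <- idx + 1L
    }
  }
  out
}

# Exact posterior weights over a list of hypergraphs at fixed (mu, phi).
exact_hyper_posterior <- function(Hs, X, mu, phi) {
  lp <- vapply(Hs, function(H) {
    log_prior_hypergraph(H, phi) + log_likelihood(X, project_labels(H), mu)
  }, numeric(1))
  w <- exp(lp - max(lp))
  w / sum(w)
}

edge_key <- function(m) apply(m, 1L, paste, collapse = " ")

# Exact marginal P(e in H | X) for every pair and triple.
exact_hyper_marginals <- function(Hs, probs, n) {
  P <- hyperinfer:::all_pairs(n)
  Tm <- hyperinfer:::all_triples(n)
  pe <- setNames(numeric(nrow(P)), edge_key(P))
  pt <- setNames(numeric(nrow(Tm)), edge_key(Tm))
  for (i in seq_along(Hs)) {
    if (nrow(Hs[[i]]$edges)) {
      k <- edge_key(Hs[[i]]$edges)
      pe[k] <- pe[k] + probs[i]
    }
    if (nrow(Hs[[i]]$triples)) {
      k <- edge_key(Hs[[i]]$triples)
      pt[k] <- pt[k] + probs[i]
    }
  }
  list(edges = pe, triples = pt)
}

# All 3^C(n,2) categorical-edge label assignments with exact posterior
# weights at fixed (mu, phi = c(q1, q2)); returns per-pair per-type marginals
# too. Rows of `labs` follow hyperinfer:::all_pairs(n).
exact_graph_posterior <- function(n, X, mu, phi) {
  P <- hyperinfer:::all_pairs(n)
  np <- nrow(P)
  labs <- as.matrix(expand.grid(rep(list(0:2), np)))
  x <- X[P]
  q1 <- phi[["q1"]]; q2 <- phi[["q2"]]
  npair <- np
  m1 <- rowSums(labs == 1L)
  m2 <- rowSums(labs == 2L)
  logprior <- m1 * log(q1) + (npair - m1 - m2) * log1p(-q1) +
    m2 * log(q2) + (npair - m2) * log1p(-q2)
  loglik <- vapply(seq_len(nrow(labs)), function(r) {
    sum(dpois(x, mu[labs[r, ] + 1L], log = TRUE))
  }, numeric(1))
  lp <- logprior + loglik
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  marg <- vapply(0:2, function(k) colSums(w * (labs == k)), numeric(np))
  list(labs = labs, probs = w, type_marginals = marg, pairs = P)
}

# Monte Carlo standard error of the mean of a (possibly autocorrelated)
# series via batch means, floored at the iid binomial SE and at 1/N.
mc_se <- function(x, n_batches = 100L) {
  N <- length(x)
  nb <- min(n_batches, N)
  bm <- tapply(x, cut(seq_len(N), nb, labels = FALSE), mean)
  se_batch <- stats::sd(bm) / sqrt(nb)
  p <- mean(x)
  max(se_batch, sqrt(p * (1 - p) / N), 1 / N, na.rm = TRUE)
}

# Empirical presence frequency of a hyperedge (given as an integer vector)
# across chain samples, as an indicator series.
chain_edge_series <- function(chain, e) {
  field <- if (length(e) == 2L) "edges" else "triples"
  key <- paste(e, collapse = " ")
  vapply(chain$samples, function(s) {
    m <- s$structure[[field]]
    nrow(m) > 0L && key %in% edge_key(m)
  }, logical(1))
}

# Hand-built chain around a list of structures (uniform weights), for
# estimator unit tests.
fake_chain <- function(structures, mu = c(0.01, 5, 10), phi = c(0.1, 0.1),
                       log_posterior = NULL) {
  model <- if (inherits(structures[[1]], "hypergraph")) "hypergraph"
           else "graph"
  if (is.null(log_posterior)) log_posterior <- rep(0, length(structures))
  samples <- lapply(seq_along(structures), function(i) {
    list(structure = structures[[i]], mu = mu, phi = phi,
         log_posterior = log_posterior[i], sweep = i)
  })
  structure(
    list(model = model, samples = samples, config = NULL, prior = NULL,
         n = structures[[1]]$n),
    class = "hyperchain"
  )
}
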