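# Planted-structure generators: best-case, worst-case and superimposed-SBM
# hypergraphs. Prior-sampled structures come from sample_hypergraph_prior().

#' Generate a best-case hypergraph
#'
#' Samples a hypergraph from the Bernoulli prior and then removes, in seeded
#' random order, every 2-edge that closes a triangle in the projected
#' interaction graph \eqn{\Delta \cup E}. In the result, groups of three
#' vertices can only be connected through a 3-edge, so neighborhood
#' information identifies 3-edges unambiguously; [triangle_fraction()] of the
#' output is 0 (or undefined when no 2-edges remain). All 3-edges of the
#' prior draw are retained.
#'
#' @param n Number of vertices (`n >= 3`).
#' @param p 3-edge existence probability.
#' @param q 2-edge existence probability.
#' @param seed Optional integer seed.
#' @return A [hypergraph()].
#' @export
generate_best_case <- function(n, p, q, seed = NULL) {
  stopifnot(n >= 3)
  with_seed(seed, {
    H <- sample_hypergraph_prior(n, list(q = q, p = p))
    M <- matrix(FALSE, n, n)
    M <- sym_assign(M, H$edges, TRUE)
    M <- sym_assign(M, covered_pairs(H), TRUE)
    covered <- matrix(FALSE, n, n)
    covered <- sym_assign(covered, covered_pairs(H), TRUE)
    keep <- rep(TRUE, nrow(H$edges))
    for (r in sample.int(nrow(H$edges))) {
      i <- H$edges[r, 1]
      j <- H$edges[r, 2]
      if (any(M[i, ] & M[j, ])) {
        keep[r] <- FALSE
        if (!covered[i, j]) M[i, j] <- M[j, i] <- FALSE
      }
    }
    hypergraph(n, edges = H$edges[keep, , drop = FALSE], triples = H$triples)
  })
}

#' Generate a worst-case hypergraph
#'
#' Builds disjoint cliques of 2-edges and independently promotes each
#' within-clique triangle to a 3-edge with probability `promote_prob`,
#' removing the three covered 2-edges (which would otherwise be hidden). In
#' the result every retained 2-edge closes a triangle in the projection, so
#' the neighborhood of a pair carries no information about its type and
#' [triangle_fraction()] is 1 whenever 2-edges remain.
#'
#' @param n_cliques Number of disjoint cliques.
#' @param clique_size Vertices per clique (`>= 3`).
#' @param promote_prob Probability of promoting each triangle to a 3-edge.
#' @return A [hypergraph()] on `n_cliques * clique_size` vertices.
#' @param seed Optional integer seed.
#' @export
generate_worst_case <- function(n_cliques, clique_size, promote_prob,
                                seed = NULL) {
  stopifnot(n_cliques >= 1, clique_size >= 3,
            promote_prob >= 0, promote_prob <= 1)
  n <- n_cliques * clique_size
  with_seed(seed, {
    edges <- list()
    triples <- list()
    for (cq in seq_len(n_cliques)) {
      verts <- (cq - 1L) * clique_size + seq_len(clique_size)
      e <- t(combn(verts, 2L))
      tri <- t(combn(verts, 3L))
      promoted <- runif(nrow(tri)) < promote_prob
      tri <- tri[promoted, , drop = FALSE]
      if (nrow(tri) > 0L) {
        cov_keys <- unique(c(
          paste(tri[, 1], tri[, 2]), paste(tri[, 1], tri[, 3]),
          paste(tri[, 2], tri[, 3])
        ))
        e <- e[!(paste(e[, 1], e[, 2]) %in% cov_keys), , drop = FALSE]
      }
      edges[[cq]] <- e
      triples[[cq]] <- tri
    }
    hypergraph(n, edges = do.call(rbind, edges),
               triples = do.call(rbind, triples))
  })
}

#' Specification of a superimposed stochastic block model
#'
#' @param sizes Community sizes (positive integers).
#' @param q Symmetric matrix of 2-edge probabilities by community pair.
#' @param p_within 3-edge probability for triples inside each community
#'   (recycled over communities).
#' @param p_between 3-edge probability for triples spanning communities.
#' @return An object of class `sbm_spec`.
#' @export
sbm_spec <- function(sizes, q, p_within, p_between) {
  sizes <- as.integer(sizes)
  K <- length(sizes)
  q <- as.matrix(q)
  stopifnot(all(sizes > 0), nrow(q) == K, ncol(q) == K,
            isTRUE(all.equal(q, t(q))), all(q >= 0), all(q <= 1),
            all(p_within >= 0), all(p_within <= 1),
            p_between >= 0, p_between <= 1)
  structure(
    list(sizes = sizes, q = q, p_within = rep_len(p_within, K),
         p_between = p_between),
    class = "sbm_spec"
  )
}

#' Generate a hypergraph from a superimposed stochastic block model
#'
#' Each 2-edge is placed independently with the probability attached to its
#' community pair; each 3-edge inside a single community is placed with that
#' community's probability, and any triple spanning two or more communities
#' with the between-community probability.
#'
#' @param spec An [sbm_spec()].
#' @param seed Optional integer seed.
#' @return A [hypergraph()] on `sum(spec$sizes)` vertices.
#' @export
generate_sbm <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sbm_spec"))
  n <- sum(spec$sizes)
  membership <- rep(seq_along(spec$sizes), spec$sizes)
  with_seed(seed, {
    P <- all_pairs(n)
    pe <- spec$q[cbind(membership[P[, 1]], membership[P[, 2]])]
    Tm <- all_triples(n)
    same <- membership[Tm[, 1]] == membership[Tm[, 2]] &
      membership[Tm[, 2]] == membership[Tm[, 3]]
    pt <- ifelse(same, spec$p_within[membership[Tm[, 1]]], spec$p_between)
    hypergraph(
      n,
      edges = P[runif(nrow(P)) < pe, , drop = FALSE],
      triples = Tm[runif(nrow(Tm)) < pt, , drop = FALSE]
    )
  })
}
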