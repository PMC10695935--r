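#' @useDynLib hyperinfer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dpois rpois dgamma dbeta rbeta qgamma pgamma rbinom runif
#'   quantile median
#' @importFrom utils read.table write.table combn
NULL

# ---- internal helpers -------------------------------------------------------

# Canonicalize a set of hyperedges given as a matrix/data.frame/vector:
# sort vertices within each row, drop duplicates, order rows lexicographically.
as_edge_matrix <- function(x, width, n, what = "hyperedge") {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0) {
    return(matrix(integer(0), ncol = width))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = width, byrow = TRUE)
  if (ncol(x) != width) {
    stop(sprintf("%s matrix must have %d columns", what, width))
  }
  storage.mode(x) <- "integer"
  if (anyNA(x)) stop(what, " indices must not be NA")
  if (any(x < 1L) || any(x > n)) {
    stop(sprintf("%s indices must lie in [1, %d]", what, n))
  }
  x <- t(apply(x, 1L, sort.int))
  if (width == 1L) x <- t(x)
  if (any(x[, -1L, drop = FALSE] == x[, -width, drop = FALSE])) {
    stop(what, " vertices must be distinct")
  }
  x <- unique(x)
  ord <- do.call(order, lapply(seq_len(width), function(j) x[, j]))
  x[ord, , drop = FALSE]
}

pair_keys <- function(m, n) (m[, 1L] - 1L) * n + m[, 2L]

# All unordered pairs / triples of 1..n, one per row, lexicographic.
all_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i, j, deparse.level = 0L)
}

all_triples <- function(n) {
  if (n < 3L) return(matrix(integer(0), ncol = 3))
  ij <- all_pairs(n)
  reps <- n - ij[, 2L]
  keep <- reps > 0L
  ij <- ij[keep, , drop = FALSE]
  reps <- reps[keep]
  k <- sequence(reps, from = ij[, 2L] + 1L)
  cbind(rep.int(ij[, 1L], reps), rep.int(ij[, 2L], reps), k,
        deparse.level = 0L)
}

sym_assign <- function(M, idx, value) {
  if (nrow(idx) > 0L) {
    M[idx] <- value
    M[idx[, 2:1, drop = FALSE]] <- value
  }
  M
}

# ---- constructors -----------------------------------------------------------

#' Latent hypergraph with 2-edges and 3-edges
#'
#' A hypergraph `H = (V, E, T)` over vertices `1..n` with a set of unordered
#' pairs (2-edges) and unordered triples (3-edges). Hyperedges are stored in
#' canonical form: vertices sorted ascending within each hyperedge, rows
#' deduplicated and ordered lexicographically.
#'
#' @param n Number of vertices (positive integer).
#' @param edges 2-edges: a two-column matrix of vertex indices (or anything
#'   coercible to one), one edge per row. May be `NULL` for no edges.
#' @param triples 3-edges: a three-column matrix of vertex indices.
#' @return An object of class `hypergraph` with fields `n`, `edges`, `triples`.
#' @examples
#' H <- hypergraph(4, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
#' project_labels(H)
#' @export
hypergraph <- function(n, edges = NULL, triples = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  H <- structure(
    list(
      n = n,
      edges = as_edge_matrix(edges, 2L, n, "2-edge"),
      triples = as_edge_matrix(triples, 3L, n, "3-edge")
    ),
    class = "hypergraph"
  )
  H
}

#' Categorical-edges graph with weak and strong edges
#'
#' The pairwise competitor structure `G = (V, E1, E2)`: disjoint sets of weak
#' (type-1) and strong (type-2) edges over vertices `1..n`.
#'
#' @param n Number of vertices.
#' @param weak Weak edges, a two-column matrix of vertex pairs.
#' @param strong Strong edges, a two-column matrix of vertex pairs; must not
#'   overlap `weak`.
#' @return An object of class `categorical_graph` with fields `n`, `weak`,
#'   `strong`.
#' @export
categorical_graph <- function(n, weak = NULL, strong = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  E1 <- as_edge_matrix(weak, 2L, n, "weak edge")
  E2 <- as_edge_matrix(strong, 2L, n, "strong edge")
  if (length(intersect(pair_keys(E1, n), pair_keys(E2, n))) > 0L) {
    stop("weak and strong edge sets must be disjoint")
  }
  structure(list(n = n, weak = E1, strong = E2), class = "categorical_graph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf(
    "Hypergraph: %d vertices, %d 2-edges, %d 3-edges\n",
    x$n, nrow(x$edges), nrow(x$triples)
  ))
  invisible(x)
}

#' @export
print.categorical_graph <- function(x, ...) {
  cat(sprintf(
    "Categorical-edges graph: %d vertices, %d weak, %d strong edges\n",
    x$n, nrow(x$weak), nrow(x$strong)
  ))
  invisible(x)
}

# ---- projection -------------------------------------------------------------

#' Pairs covered by at least one 3-edge
#'
#' Returns the set \eqn{\Delta} of vertex pairs contained in at least one
#' 3-edge of the hypergraph; pairs in \eqn{\Delta} project to type-2
#' interactions.
#'
#' @param H A [hypergraph()].
#' @return A two-column integer matrix of covered pairs, canonical order.
#' @export
covered_pairs <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  Tm <- H$triples
  if (nrow(Tm) == 0L) return(matrix(integer(0), ncol = 2))
  pairs <- rbind(Tm[, c(1, 2), drop = FALSE],
                 Tm[, c(1, 3), drop = FALSE],
                 Tm[, c(2, 3), drop = FALSE])
  as_edge_matrix(pairs, 2L, H$n, "covered pair")
}

#' Project a latent structure to pairwise interaction types
#'
#' Maps a structure to its label matrix \eqn{\ell_{ij} \in \{0, 1, 2\}}.
#' For a hypergraph, a pair covered by any 3-edge has type 2, a pair connected
#' only by a 2-edge has type 1, and all remaining pairs have type 0; 2-edges
#' lying inside covered pairs are thereby hidden. For a categorical-edges
#' graph, strong edges map to 2 and weak edges to 1.
#'
#' @param S A [hypergraph()] or [categorical_graph()].
#' @return An `n x n` symmetric integer matrix with entries in `{0, 1, 2}` and
#'   a zero (ignored) diagonal.
#' @export
project_labels <- function(S) UseMethod("project_labels")

#' @export
project_labels.hypergraph <- function(S) {
  L <- matrix(0L, S$n, S$n)
  L <- sym_assign(L, S$edges, 1L)
  L <- sym_assign(L, covered_pairs(S), 2L)
  L
}

#' @export
project_labels.categorical_graph <- function(S) {
  if (length(intersect(pair_keys(S$weak, S$n), pair_keys(S$strong, S$n))) > 0L) {
    stop("weak and strong edge sets overlap")
  }
  L <- matrix(0L, S$n, S$n)
  L <- sym_assign(L, S$weak, 1L)
  L <- sym_assign(L, S$strong, 2L)
  L
}

#' Hyperedges hidden by other hyperedges
#'
#' A hyperedge is hidden when removing it leaves the projected label matrix --
#' and therefore the likelihood of any dataset -- unchanged: a 2-edge lying
#' inside a pair covered by a 3-edge, or a 3-edge all of whose pairs remain
#' covered by other 3-edges. Hidden hyperedges are unrecoverable from pairwise
#' data. Each hyperedge is tested operationally by recomputing the projection
#' with that single hyperedge removed.
#'
#' @param H A [hypergraph()].
#' @return A list with `edges` and `triples`: the hidden hyperedges, in the
#'   same matrix form as in the hypergraph.
#' @export
hidden_hyperedges <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  L <- project_labels(H)
  hidden_e <- logical(nrow(H$edges))
  for (r in seq_len(nrow(H$edges))) {
    Hr <- H
    Hr$edges <- H$edges[-r, , drop = FALSE]
    hidden_e[r] <- identical(project_labels(Hr), L)
  }
  hidden_t <- logical(nrow(H$triples))
  for (r in seq_len(nrow(H$triples))) {
    Hr <- H
    Hr$triples <- H$triples[-r, , drop = FALSE]
    hidden_t[r] <- identical(project_labels(Hr), L)
  }
  list(
    edges = H$edges[hidden_e, , drop = FALSE],
    triples = H$triples[hidden_t, , drop = FALSE]
  )
}
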