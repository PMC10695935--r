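# Point estimators derived from a posterior chain.

check_chain <- function(chain) {
  if (!inherits(chain, "hyperchain") || length(chain$samples) == 0L) {
    stop("chain must be a non-empty hyperchain")
  }
  invisible(chain)
}

#' Maximum a posteriori structure estimate
#'
#' Returns the structure of the retained sample with the highest recorded
#' log-posterior, the standard sample-based surrogate for the posterior
#' argmax. Ties are broken by the earliest sample.
#'
#' @param chain A `hyperchain` from [run_chain()].
#' @return The MAP structure ([hypergraph()] or [categorical_graph()]).
#' @export
map_estimate <- function(chain) {
  check_chain(chain)
  lp <- vapply(chain$samples, `[[`, numeric(1), "log_posterior")
  chain$samples[[which.max(lp)]]$structure
}

edge_frequencies <- function(mats, n, width) {
  keys <- unlist(lapply(mats, function(m) {
    if (nrow(m) == 0L) return(character(0))
    apply(m, 1L, paste, collapse = " ")
  }))
  if (!length(keys)) return(integer(0))
  table(keys)
}

keys_to_matrix <- function(keys, width) {
  if (!length(keys)) return(matrix(integer(0), ncol = width))
  m <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  m
}

#' Edge-wise marginal structure estimate
#'
#' Returns the structure containing exactly the hyperedges whose empirical
#' marginal posterior probability across the chain is strictly above 0.5.
#' For the categorical-edges model, each pair's three label states are
#' considered jointly: the modal state is kept only if its frequency exceeds
#' 0.5, which guarantees disjoint weak/strong sets.
#'
#' @param chain A `hyperchain` from [run_chain()].
#' @return A [hypergraph()] or [categorical_graph()].
#' @export
edgewise_estimate <- function(chain) {
  check_chain(chain)
  N <- length(chain$samples)
  n <- chain$n
  if (chain$model == "hypergraph") {
    fe <- edge_frequencies(lapply(chain$samples,
                                  function(s) s$structure$edges), n, 2L)
    ft <- edge_frequencies(lapply(chain$samples,
                                  function(s) s$structure$triples), n, 3L)
    hypergraph(
      n,
      edges = keys_to_matrix(names(fe)[fe / N > 0.5], 2L),
      triples = keys_to_matrix(names(ft)[ft / N > 0.5], 3L)
    )
  } else {
    cnt <- label_count_array(chain)
    pairs <- all_pairs(n)
    freq <- cnt / N
    best <- max.col(freq, ties.method = "first")
    keep <- freq[cbind(seq_len(nrow(freq)), best)] > 0.5
    lab <- ifelse(keep, best - 1L, 0L)
    categorical_graph(
      n,
      weak = pairs[lab == 1L, , drop = FALSE],
      strong = pairs[lab == 2L, , drop = FALSE]
    )
  }
}

# Per-pair label counts over the chain: rows follow all_pairs(n), columns are
# types 0..2.
label_count_array <- function(chain) {
  n <- chain$n
  pairs <- all_pairs(n)
  cnt <- matrix(0L, nrow(pairs), 3L)
  for (s in chain$samples) {
    lab <- project_labels(s$structure)[pairs]
    for (k in 0:2) cnt[, k + 1L] <- cnt[, k + 1L] + (lab == k)
  }
  cnt
}

#' Maximum-marginal interaction-type estimate
#'
#' For every pair, projects each posterior sample's structure to labels and
#' returns the modal interaction type; ties are broken uniformly at random
#' (reproducibly under `seed`).
#'
#' @param chain A `hyperchain` from [run_chain()].
#' @param seed Optional integer seed for tie-breaking.
#' @return A label matrix with entries in `{0, 1, 2}`.
#' @export
marginal_type_estimate <- function(chain, seed = NULL) {
  check_chain(chain)
  n <- chain$n
  cnt <- label_count_array(chain)
  with_seed(seed, {
    lab <- apply(cnt, 1L, function(v) {
      best <- which(v == max(v))
      if (length(best) > 1L) best <- sample(best, 1L)
      best - 1L
    })
    L <- matrix(0L, n, n)
    sym_assign(L, all_pairs(n), as.integer(lab))
  })
}
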