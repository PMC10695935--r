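test_that("covered pairs expand 3-edges into their three vertex pairs", {
  H <- hypergraph(3, triples = rbind(c(1, 2, 3)))
  expect_equal(covered_pairs(H), rbind(c(1, 2), c(1, 3), c(2, 3)))

  expect_equal(nrow(covered_pairs(hypergraph(4, edges = rbind(c(1, 4))))), 0L)

  H2 <- hypergraph(4, triples = rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(covered_pairs(H2),
               rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
})

test_that("hypergraph projection assigns types with 3-edges dominating", {
  H <- hypergraph(3, edges = rbind(c(1, 2)))
  L <- project_labels(H)
  expect_equal(L[1, 2], 1L)
  expect_equal(L[1, 3], 0L)
  expect_equal(L[2, 3], 0L)

  # a 2-edge under a 3-edge is hidden: all three pairs read type 2
  H <- hypergraph(3, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
  L <- project_labels(H)
  expect_equal(L[upper.tri(L)], rep(2L, 3))

  H <- hypergraph(4, edges = rbind(c(3, 4)), triples = rbind(c(1, 2, 3)))
  L <- project_labels(H)
  expect_equal(L[1, 2], 2L)
  expect_equal(L[1, 3], 2L)
  expect_equal(L[2, 3], 2L)
  expect_equal(L[3, 4], 1L)
  expect_equal(L[1, 4], 0L)
  expect_equal(L[2, 4], 0L)
})

test_that("categorical-graph projection maps weak/strong to 1/2", {
  G <- categorical_graph(3, weak = rbind(c(1, 2)), strong = rbind(c(2, 3)))
  L <- project_labels(G)
  expect_equal(L[1, 2], 1L)
  expect_equal(L[2, 3], 2L)
  expect_equal(L[1, 3], 0L)

  expect_equal(project_labels(categorical_graph(2)), matrix(0L, 2, 2))

  G <- categorical_graph(4, weak = rbind(c(1, 2), c(3, 4)),
                         strong = rbind(c(1, 3)))
  L <- project_labels(G)
  expect_equal(sum(L[upper.tri(L)] == 1L), 2L)
  expect_equal(sum(L[upper.tri(L)] == 2L), 1L)

  expect_error(categorical_graph(3, weak = rbind(c(1, 2)),
                                 strong = rbind(c(1, 2))),
               "disjoint")
})

test_that("hidden hyperedges are exactly those whose removal keeps labels", {
  h <- hidden_hyperedges(
    hypergraph(3, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
  )
  expect_equal(h$edges, rbind(c(1L, 2L)))
  expect_equal(nrow(h$triples), 0L)

  h <- hidden_hyperedges(hypergraph(4, triples = rbind(c(1, 2, 3))))
  expect_equal(nrow(h$edges), 0L)
  expect_equal(nrow(h$triples), 0L)

  # mutually covering triples: every triple's pairs stay covered without it
  H <- hypergraph(4, triples = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4),
                                     c(2, 3, 4)))
  h <- hidden_hyperedges(H)
  expect_equal(nrow(h$triples), 4L)
})

test_that("projection invariants hold on random hypergraphs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    H <- sample_hypergraph_prior(n, list(q = 0.4, p = 0.25))
    L <- project_labels(H)
    # label 2 exactly on covered pairs
    cov <- matrix(FALSE, n, n)
    cp <- covered_pairs(H)
    if (nrow(cp)) {
      cov[cp] <- TRUE
      cov[cp[, 2:1, drop = FALSE]] <- TRUE
    }
    expect_identical(L == 2L, cov)
    # removing any reported hidden hyperedge leaves the labels unchanged
    h <- hidden_hyperedges(H)
    for (r in seq_len(nrow(h$edges))) {
      Hr <- H
      keep <- !(H$edges[, 1] == h$edges[r, 1] & H$edges[, 2] == h$edges[r, 2])
      Hr$edges <- H$edges[keep, , drop = FALSE]
      expect_identical(project_labels(Hr), L)
    }
    for (r in seq_len(nrow(h$triples))) {
      Hr <- H
      keep <- !(H$triples[, 1] == h$triples[r, 1] &
                  H$triples[, 2] == h$triples[r, 2] &
                  H$triples[, 3] == h$triples[r, 3])
      Hr$triples <- H$triples[keep, , drop = FALSE]
      expect_identical(project_labels(Hr), L)
    }
  }
})

test_that("graph projection label counts match edge-set sizes", {
  set.seed(7)
  for (rep in 1:10) {
    G <- sample_graph_prior(6, list(q1 = 0.3, q2 = 0.2))
    L <- project_labels(G)
    expect_equal(sum(L[upper.tri(L)] == 1L), nrow(G$weak))
    expect_equal(sum(L[upper.tri(L)] == 2L), nrow(G$strong))
  }
})

test_that("constructors canonicalize and validate hyperedges", {
  H <- hypergraph(5, edges = rbind(c(3, 1), c(1, 3), c(2, 4)),
                  triples = rbind(c(5, 2, 1)))
  expect_equal(H$edges, rbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(H$triples, rbind(c(1L, 2L, 5L)))
  expect_error(hypergraph(3, edges = rbind(c(1, 4))), "indices")
  expect_error(hypergraph(3, edges = rbind(c(2, 2))), "distinct")
  expect_error(hypergraph(4, triples = rbind(c(1, 2))), "columns")
})
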