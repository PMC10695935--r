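H_a <- hypergraph(4, edges = rbind(c(1, 2)))
H_b <- hypergraph(4, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
H_c <- hypergraph(4, edges = rbind(c(3, 4)))

test_that("MAP estimator picks the highest-posterior sample, earliest on ties", {
  ch <- fake_chain(list(H_a), log_posterior = -5)
  expect_identical(map_estimate(ch), H_a)

  ch <- fake_chain(list(H_a, H_b, H_c), log_posterior = c(-10, -2, -7))
  expect_identical(map_estimate(ch), H_b)

  ch <- fake_chain(list(H_a, H_c), log_posterior = c(-3, -3))
  expect_identical(map_estimate(ch), H_a)

  expect_error(map_estimate(fake_chain(list(H_a))$samples), "hyperchain")
})

test_that("edge-wise estimator applies the strict 0.5 marginal rule", {
  # hyperedge in 251 of 500 samples is kept; in exactly 250 it is dropped
  mk <- function(k) {
    structures <- c(replicate(k, H_a, simplify = FALSE),
                    replicate(500 - k, hypergraph(4), simplify = FALSE))
    edgewise_estimate(fake_chain(structures))
  }
  expect_equal(mk(251)$edges, rbind(c(1L, 2L)))
  expect_equal(nrow(mk(250)$edges), 0L)

  ch <- fake_chain(replicate(10, H_b, simplify = FALSE))
  expect_identical(edgewise_estimate(ch), H_b)
})

test_that("edge-wise estimator on the graph model never overlaps sets", {
  G1 <- categorical_graph(3, weak = rbind(c(1, 2)))
  G2 <- categorical_graph(3, strong = rbind(c(1, 2)))
  # 5 weak / 4 strong / 2 empty for pair (1,2): no state passes 0.5
  ch <- fake_chain(c(replicate(5, G1, simplify = FALSE),
                     replicate(4, G2, simplify = FALSE),
                     replicate(2, categorical_graph(3), simplify = FALSE)))
  est <- edgewise_estimate(ch)
  expect_equal(nrow(est$weak) + nrow(est$strong), 0L)
  # 8 weak / 3 strong: weak wins with marginal > 0.5
  ch <- fake_chain(c(replicate(8, G1, simplify = FALSE),
                     replicate(3, G2, simplify = FALSE)))
  est <- edgewise_estimate(ch)
  expect_equal(est$weak, rbind(c(1L, 2L)))
  expect_equal(nrow(est$strong), 0L)
})

test_that("maximum-marginal types take the per-pair mode", {
  structures <- c(replicate(400, H_b, simplify = FALSE),
                  replicate(100, H_a, simplify = FALSE))
  L <- marginal_type_estimate(fake_chain(structures))
  expect_equal(L[1, 2], 2L)
  expect_equal(L[1, 3], 2L)

  ch1 <- fake_chain(list(H_b))
  expect_identical(marginal_type_estimate(ch1), project_labels(H_b))
})

test_that("marginal-type ties break at random but reproducibly", {
  structures <- c(replicate(250, H_a, simplify = FALSE),
                  replicate(250, hypergraph(4), simplify = FALSE))
  ch <- fake_chain(structures)
  draws <- vapply(1:40, function(s) {
    marginal_type_estimate(ch, seed = s)[1, 2]
  }, integer(1))
  expect_setequal(unique(draws), c(0L, 1L))
  expect_identical(marginal_type_estimate(ch, seed = 7),
                   marginal_type_estimate(ch, seed = 7))
})

test_that("marginal-type estimate is invariant to chain order", {
  set.seed(51)
  structures <- replicate(30, sample_hypergraph_prior(5, list(q = 0.5,
                                                              p = 0.3)),
                          simplify = FALSE)
  ch <- fake_chain(structures)
  ch_rev <- fake_chain(rev(structures))
  expect_identical(marginal_type_estimate(ch, seed = 1),
                   marginal_type_estimate(ch_rev, seed = 1))
})

test_that("estimators agree with exact marginals on an enumerable instance", {
  Htrue <- hypergraph(3, edges = rbind(c(1, 3)))
  mu <- c(0.1, 5, 12)
  phi <- c(q = 0.25, p = 0.2)
  X <- sample_observations(project_labels(Htrue), mu, seed = 52)
  Hs <- enumerate_hypergraphs(3)
  probs <- exact_hyper_posterior(Hs, X, mu, as.list(phi))
  marg <- exact_hyper_marginals(Hs, probs, 3)
  ch <- run_chain(X, sampler_config("hypergraph", n_samples = 4000,
                                    burn_in = 200, thinning = 2,
                                    update_mu = FALSE, update_phi = FALSE,
                                    seed = 53),
                  init = list(structure = hypergraph(3), mu = mu, phi = phi))
  # MAP matches the exact argmax structure
  exact_map <- Hs[[which.max(probs)]]
  expect_identical(map_estimate(ch), exact_map)
  # edge-wise frequencies within Monte Carlo error of exact marginals
  for (key in names(marg$edges)) {
    series <- chain_edge_series(ch, as.integer(strsplit(key, " ")[[1]]))
    expect_lt(abs(mean(series) - marg$edges[[key]]), 3 * mc_se(series))
  }
})
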