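test_that("initialization recovers well-separated rates", {
  # 34-vertex instance in the rate regime of the small-network case study
  set.seed(21)
  H <- sample_hypergraph_prior(34, list(q = 0.1, p = 0.01))
  L <- project_labels(H)
  X <- sample_observations(L, c(0.01, 20, 30))
  init <- init_heuristic(X, "hypergraph")
  expect_lt(abs(init$mu[2] - 20) / 20, 0.2)
  expect_lt(abs(init$mu[3] - 30) / 30, 0.2)
  expect_lt(init$mu[1], 0.2)
  expect_true(all(diff(init$mu) > 0))
  expect_s3_class(init$structure, "hypergraph")
  # initial structure reproduces the label partition where visible
  expect_true(all(project_labels(init$structure)[upper.tri(L)] %in% 0:2))
})

test_that("initialization falls back gracefully on degenerate data", {
  X <- matrix(0L, 6, 6)
  init <- init_heuristic(X, "hypergraph")
  expect_equal(nrow(init$structure$edges), 0L)
  expect_equal(nrow(init$structure$triples), 0L)
  expect_true(all(diff(init$mu) > 0))

  initg <- init_heuristic(X, "graph")
  expect_equal(nrow(initg$structure$weak) + nrow(initg$structure$strong), 0L)
})

test_that("gibbs rate update matches the conjugate gamma posterior", {
  # one type-0 pair with x = 3 under gamma(1, 1): posterior gamma(4, 2)
  X <- matrix(c(0L, 3L, 3L, 0L), 2, 2)
  L <- matrix(0L, 2, 2)
  spec <- prior_spec(mu_shape = 1, mu_rate = 1)
  set.seed(31)
  draws <- replicate(10000, gibbs_update_mu(X, L, spec, model = "none")[1])
  post_mean <- 4 / 2
  post_sd <- sqrt(4) / 2
  expect_lt(abs(mean(draws) - post_mean), 3 * post_sd / sqrt(10000))
  expect_lt(abs(stats::sd(draws) - post_sd), 0.05)
})

test_that("gibbs rate update respects the ordering constraints", {
  set.seed(32)
  H <- sample_hypergraph_prior(8, list(q = 0.3, p = 0.1))
  L <- project_labels(H)
  X <- sample_observations(L, c(0.5, 5, 9))
  for (rep in 1:200) {
    mu_g <- gibbs_update_mu(X, L, model = "graph")
    expect_true(mu_g[1] < mu_g[2] && mu_g[2] < mu_g[3])
    mu_h <- gibbs_update_mu(X, L, model = "hypergraph")
    expect_true(mu_h[1] < mu_h[2] && mu_h[1] < mu_h[3])
  }
  # with a current state, truncation respects it
  mu_c <- c(1, 2, 3)
  for (rep in 1:100) {
    mu <- gibbs_update_mu(X, L, model = "graph", mu_current = mu_c)
    expect_true(mu[1] < mu_c[2] && mu[2] > mu[1] && mu[3] > mu[2])
  }
})

test_that("with no data for a type the update reproduces its prior", {
  # labels all zero: types 1 and 2 carry no pairs, so their draws are prior
  X <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  L <- matrix(0L, 2, 2)
  spec <- prior_spec(mu_shape = 2, mu_rate = 0.5)
  set.seed(33)
  draws <- replicate(4000, gibbs_update_mu(X, L, spec, model = "none")[2])
  ks <- stats::ks.test(draws, stats::pgamma, shape = 2, rate = 0.5)
  expect_gt(ks$p.value, 1e-3)
})

test_that("gibbs probability update matches the conjugate beta posterior", {
  H <- hypergraph(3, edges = rbind(c(1, 2), c(1, 3), c(2, 3)))
  set.seed(34)
  draws <- replicate(10000, gibbs_update_phi(H)[["q"]])
  # q ~ beta(4, 1): mean 0.8
  expect_lt(abs(mean(draws) - 0.8), 3 * sqrt(4 / (25 * 6)) / sqrt(10000))
  expect_true(all(draws > 0 & draws < 1))

  H0 <- hypergraph(6)
  draws0 <- replicate(10000, gibbs_update_phi(H0)[["q"]])
  expect_lt(abs(mean(draws0) - 1 / (choose(6, 2) + 2)), 3e-3)

  G <- categorical_graph(4, weak = rbind(c(1, 2)), strong = rbind(c(3, 4)))
  phi <- gibbs_update_phi(G, seed = 1)
  expect_named(phi, c("q1", "q2"))
})

test_that("flipping a hidden 2-edge leaves the likelihood unchanged", {
  H_with <- hypergraph(3, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
  H_without <- hypergraph(3, triples = rbind(c(1, 2, 3)))
  X <- sample_observations(project_labels(H_with), c(0.1, 5, 12), seed = 35)
  mu <- c(0.1, 5, 12)
  expect_equal(log_likelihood(X, project_labels(H_with), mu),
               log_likelihood(X, project_labels(H_without), mu))
})

test_that("structure updates are valid and seeded", {
  H <- hypergraph(5, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
  X <- sample_observations(project_labels(H), c(0.1, 5, 12), seed = 36)
  up1 <- mh_update_structure(H, X, c(0.1, 5, 12), c(q = 0.3, p = 0.2),
                             n_proposals = 200, seed = 37)
  up2 <- mh_update_structure(H, X, c(0.1, 5, 12), c(q = 0.3, p = 0.2),
                             n_proposals = 200, seed = 37)
  expect_identical(up1, up2)
  expect_s3_class(up1, "hypergraph")

  G <- categorical_graph(5, weak = rbind(c(1, 2)))
  upg <- mh_update_structure(G, X, c(0.1, 5, 12), c(q1 = 0.3, q2 = 0.2),
                             n_proposals = 200, seed = 38)
  expect_s3_class(upg, "categorical_graph")
  expect_length(intersect(hyperinfer:::pair_keys(upg$weak, 5),
                          hyperinfer:::pair_keys(upg$strong, 5)), 0L)
})

test_that("chains are reproducible and respect rate ordering", {
  set.seed(41)
  H <- sample_hypergraph_prior(6, list(q = 0.3, p = 0.1))
  X <- sample_observations(project_labels(H), c(0.1, 6, 14))
  cfg <- sampler_config("hypergraph", n_samples = 40, burn_in = 50,
                        thinning = 2, seed = 99)
  ch1 <- run_chain(X, cfg)
  ch2 <- run_chain(X, cfg)
  expect_identical(lapply(ch1$samples, `[[`, "log_posterior"),
                   lapply(ch2$samples, `[[`, "log_posterior"))
  expect_identical(lapply(ch1$samples, `[[`, "structure"),
                   lapply(ch2$samples, `[[`, "structure"))
  for (s in ch1$samples) {
    expect_true(s$mu[1] < s$mu[2] && s$mu[1] < s$mu[3])
  }
  cfg_g <- sampler_config("graph", n_samples = 40, burn_in = 50,
                          thinning = 2, seed = 99)
  for (s in run_chain(X, cfg_g)$samples) {
    expect_true(s$mu[1] < s$mu[2] && s$mu[2] < s$mu[3])
  }
  expect_error(run_chain(matrix(0L, 2, 2),
                         sampler_config("hypergraph", n_samples = 2,
                                        burn_in = 1, seed = 1)),
               "at least 3")
})

test_that("stored log-posteriors re-evaluate from the modules", {
  set.seed(43)
  H <- sample_hypergraph_prior(6, list(q = 0.3, p = 0.1))
  X <- sample_observations(project_labels(H), c(0.1, 6, 14))
  spec <- prior_spec()
  ch <- run_chain(X, sampler_config("hypergraph", n_samples = 30,
                                    burn_in = 30, thinning = 2, seed = 44),
                  spec)
  for (s in ch$samples) {
    expect_equal(
      s$log_posterior,
      log_likelihood(X, project_labels(s$structure), s$mu) +
        log_prior_hypergraph(s$structure, as.list(s$phi)) +
        log_hyperprior(s$mu, s$phi, spec),
      tolerance = 1e-9
    )
  }
  chg <- run_chain(X, sampler_config("graph", n_samples = 30, burn_in = 30,
                                     thinning = 2, seed = 44), spec)
  for (s in chg$samples) {
    expect_equal(
      s$log_posterior,
      log_likelihood(X, project_labels(s$structure), s$mu) +
        log_prior_graph(s$structure, as.list(s$phi)) +
        log_hyperprior(s$mu, s$phi, spec),
      tolerance = 1e-9
    )
  }
})

test_that("chain marginals agree with exhaustive enumeration at n = 3", {
  # fixed (mu, phi): the structure moves alone must target the exact
  # posterior over all 16 hypergraphs
  Htrue <- hypergraph(3, edges = rbind(c(1, 2)), triples = rbind(c(1, 2, 3)))
  mu <- c(0.1, 5, 12)
  phi <- c(q = 0.3, p = 0.2)
  X <- sample_observations(project_labels(Htrue), mu, seed = 45)
  Hs <- enumerate_hypergraphs(3)
  probs <- exact_hyper_posterior(Hs, X, mu, as.list(phi))
  marg <- exact_hyper_marginals(Hs, probs, 3)
  init <- list(structure = hypergraph(3), mu = mu, phi = phi)
  ch <- run_chain(X, sampler_config("hypergraph", n_samples = 4000,
                                    burn_in = 200, thinning = 2,
                                    update_mu = FALSE, update_phi = FALSE,
                                    seed = 46),
                  init = init)
  for (key in names(marg$edges)) {
    series <- chain_edge_series(ch, as.integer(strsplit(key, " ")[[1]]))
    expect_lt(abs(mean(series) - marg$edges[[key]]), 3 * mc_se(series))
  }
  for (key in names(marg$triples)) {
    series <- chain_edge_series(ch, as.integer(strsplit(key, " ")[[1]]))
    expect_lt(abs(mean(series) - marg$triples[[key]]), 3 * mc_se(series))
  }
})
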