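labels_from <- function(n, vals) {
  L <- matrix(0L, n, n)
  P <- hyperinfer:::all_pairs(n)
  L[P] <- as.integer(vals)
  L[P[, 2:1]] <- as.integer(vals)
  L
}

test_that("confusion matrix counts true-vs-predicted pairs", {
  L <- labels_from(3, c(0, 1, 2))
  C <- confusion_matrix(L, L)
  expect_equal(diag(C), c(`0` = 1L, `1` = 1L, `2` = 1L),
               ignore_attr = TRUE)
  expect_equal(sum(C), choose(3, 2))

  pred <- labels_from(3, c(0, 2, 2))
  C <- confusion_matrix(L, pred)
  expect_equal(C[1, 1], 1L)
  expect_equal(C[2, 3], 1L)
  expect_equal(C[3, 3], 1L)
  expect_equal(sum(C), 3L)

  set.seed(61)
  for (rep in 1:5) {
    La <- labels_from(6, sample(0:2, 15, replace = TRUE))
    Lb <- labels_from(6, sample(0:2, 15, replace = TRUE))
    expect_equal(sum(confusion_matrix(La, Lb)), choose(6, 2))
    expect_true(all(diag(confusion_matrix(La, La)) ==
                      tabulate(La[upper.tri(La)] + 1L, 3L)))
  }
  expect_error(confusion_matrix(labels_from(3, c(0, 0, 0)),
                                labels_from(4, rep(0, 6))), "same dimension")
})

test_that("relative reconstruction error follows its confusion-matrix form", {
  L <- labels_from(3, c(0, 1, 2))
  expect_equal(reconstruction_error(confusion_matrix(L, L)), 0)

  C <- matrix(0L, 3, 3)
  C[2, 1] <- 1L  # c10
  C[2, 2] <- 1L  # c11
  expect_equal(reconstruction_error(C), 0.5)

  Cbad <- matrix(0L, 3, 3)
  Cbad[2, 1] <- 3L
  Cbad[3, 2] <- 2L
  expect_equal(reconstruction_error(Cbad), 1)

  Cnone <- matrix(0L, 3, 3)
  Cnone[1, 1] <- 10L
  expect_true(is.na(reconstruction_error(Cnone)))
})

test_that("type proportions sum to one and track predictions", {
  C <- diag(c(5L, 5L, 5L))
  expect_equal(type_proportions(C), c(1, 1, 1) / 3, ignore_attr = TRUE)

  Call0 <- matrix(0L, 3, 3)
  Call0[, 1] <- c(3L, 2L, 1L)
  expect_equal(type_proportions(Call0), c(1, 0, 0), ignore_attr = TRUE)

  L <- labels_from(3, c(0, 1, 2))
  pred <- labels_from(3, c(0, 2, 2))
  expect_equal(type_proportions(confusion_matrix(L, pred)),
               c(1 / 3, 0, 2 / 3), ignore_attr = TRUE)
})

test_that("label entropy uses base 3 with the 0 log 0 convention", {
  expect_equal(label_entropy(c(1, 1, 1) / 3), 1)
  expect_equal(label_entropy(c(1, 0, 0)), 0)
  expect_equal(label_entropy(c(0.5, 0.5, 0)), log(2, base = 3))
})

test_that("triangle fraction matches a brute-force all-triples oracle", {
  expect_equal(triangle_fraction(
    hypergraph(3, edges = rbind(c(1, 2), c(1, 3), c(2, 3)))
  ), 1)
  expect_true(is.na(triangle_fraction(hypergraph(4,
                                                 triples = rbind(c(1, 2, 3))))))

  oracle <- function(H) {
    M <- matrix(FALSE, H$n, H$n)
    put <- function(M, m) {
      if (nrow(m)) {
        M[m] <- TRUE
        M[m[, 2:1, drop = FALSE]] <- TRUE
      }
      M
    }
    M <- put(M, H$edges)
    M <- put(M, covered_pairs(H))
    tri <- hyperinfer:::all_triples(H$n)
    closed <- tri[M[tri[, c(1, 2)]] & M[tri[, c(1, 3)]] & M[tri[, c(2, 3)]], ,
                  drop = FALSE]
    in_closed <- matrix(FALSE, H$n, H$n)
    if (nrow(closed)) {
      for (cc in list(c(1, 2), c(1, 3), c(2, 3))) {
        in_closed <- put(in_closed, closed[, cc, drop = FALSE])
      }
    }
    mean(in_closed[H$edges])
  }
  set.seed(62)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    H <- sample_hypergraph_prior(n, list(q = 0.35, p = 0.08))
    if (nrow(H$edges) == 0L) next
    expect_equal(triangle_fraction(H), oracle(H))
  }
})

test_that("predictive residuals are centred when the chain sits at truth", {
  set.seed(63)
  H <- sample_hypergraph_prior(12, list(q = 0.3, p = 0.03))
  mu <- c(0.2, 8, 16)
  L <- project_labels(H)
  X <- sample_observations(L, mu)
  ch <- fake_chain(replicate(20, H, simplify = FALSE), mu = mu)
  res <- residual_sums(X, ch, n_draws = 200, seed = 64)
  for (k in 0:2) {
    npairs_k <- sum(L[upper.tri(L)] == k)
    sd_k <- sqrt(npairs_k * mu[k + 1] * (1 + 1 / 200))
    expect_lt(abs(res$mean[[k + 1]]), 3 * sd_k)
  }
  expect_identical(res, residual_sums(X, ch, n_draws = 200, seed = 64))
  expect_equal(res$sum, res$mean * 200)
})

test_that("predictive residuals expose a misspecified rate", {
  set.seed(65)
  H <- sample_hypergraph_prior(12, list(q = 0.3, p = 0.03))
  mu <- c(0.2, 8, 16)
  L <- project_labels(H)
  X <- sample_observations(L, mu)
  ch_wrong <- fake_chain(list(H), mu = 2 * mu)
  res <- residual_sums(X, ch_wrong, n_draws = 200, seed = 66)
  for (k in 0:2) {
    idx <- L[upper.tri(L)] == k
    expected <- -sum(mu[k + 1] * idx)  # E[x - x~] = mu - 2 mu per pair
    sd_k <- sqrt(sum(idx) * (mu[k + 1] + 2 * mu[k + 1] / 200))
    expect_lt(abs(res$mean[[k + 1]] - expected), 3 * sd_k)
  }
})
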