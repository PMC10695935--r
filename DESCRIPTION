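Package: hyperinfer
Title: Bayesian Reconstruction of Hypergraphs from Noisy Pairwise Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs latent higher-order network structure from noisy
    integer-valued pairwise observation counts. Implements a Poisson
    observation model over three interaction types, Bernoulli hyperedge
    priors for a hypergraph (2-edges and 3-edges) and for a competing
    categorical-edges graph (weak and strong edges), and
    Metropolis-within-Gibbs samplers targeting the joint posterior over
    structure, Poisson rates and structure hyperparameters. Provides
    posterior point estimators (maximum a posteriori, edge-wise marginal,
    maximum-marginal interaction types), evaluation statistics (confusion
    matrix, relative reconstruction error, label entropy, projected-triangle
    fraction, posterior-predictive residual sums), optimal Poisson-threshold
    baseline classifiers, and planted-structure generators (prior-sampled,
    best-case, worst-case, superimposed stochastic block model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
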