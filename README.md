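# hyperinfer

Bayesian reconstruction of latent hypergraphs from noisy pairwise
observation counts.

Many interaction datasets are collected pairwise — numbers of recorded
contacts, co-occurrences or interaction events $x_{ij}$ between units $i$
and $j$ — even when some of the underlying interactions involve three units
at once. `hyperinfer` is for researchers who want to ask, from such a count
matrix alone, *which pairs interact, how strongly, and which strong
interactions are really the shadow of a three-way interaction*.

## The model

Each pair has a latent interaction type
$\ell_{ij} \in \{0, 1, 2\}$ (none / weak / strong) and counts are
independent Poisson draws,

$$P(X \mid \mathcal{S}, \mu) = \prod_{i<j}
  \frac{\mu_{\ell_{ij}}^{x_{ij}}}{x_{ij}!}\, e^{-\mu_{\ell_{ij}}},
  \qquad \mu = (\mu_0, \mu_1, \mu_2).$$

The types come from one of two latent structures:

* **hypergraph** $H = (V, E, T)$: pairs covered by a 3-edge in $T$ are
  strong, pairs joined only by a 2-edge in $E$ weak. Hyperedges exist
  independently a priori (2-edges with probability $q$, 3-edges with $p$);
* **categorical-edges graph** $G = (V, E_1, E_2)$: disjoint weak and strong
  edge sets, the purely pairwise competitor.

A Metropolis-within-Gibbs sampler (`run_chain()`) targets the joint
posterior $P(\mathcal{S}, \mu, \phi \mid X)$ with conjugate gamma/beta
updates for the rates and structure probabilities and single-hyperedge flip
proposals for the structure, under the identifiability constraints
$\mu_0 < \mu_1$, $\mu_0 < \mu_2$ (hypergraph) or
$\mu_0 < \mu_1 < \mu_2$ (graph). Point estimates come from
`map_estimate()`, `edgewise_estimate()` (marginal probability > 0.5) and
`marginal_type_estimate()` (per-pair modal type); evaluation against a
planted truth uses the confusion matrix, the relative reconstruction error
$\epsilon$, predicted-type proportions and their base-3 entropy, the
projected-triangle fraction $E_\Delta$, and posterior-predictive residual
sums. Optimal weighted-Poisson threshold baselines
(`optimal_thresholds()`, `threshold_classify()`) and planted-structure
generators (`generate_best_case()`, `generate_worst_case()`,
`generate_sbm()`) complete the toolbox. See the vignette in
`vignettes/hypergraph-reconstruction.Rmd` for the methods in full.

## A worked example

Plant a clique-structured hypergraph, observe it noisily, and reconstruct:

```r
library(hyperinfer)

H <- generate_worst_case(n_cliques = 4, clique_size = 5,
                         promote_prob = 0.19, seed = 42)
H
#> Hypergraph: 20 vertices, 22 2-edges, 6 3-edges
triangle_fraction(H)
#> [1] 1

X <- sample_observations(project_labels(H), mu = c(0.01, 25, 50), seed = 43)
chain <- run_chain(X, sampler_config("hypergraph", seed = 44))
chain
#> Posterior chain (hypergraph model): 500 samples over 20 vertices
#>   log-posterior: min -270.61, median -257.00, max -249.91

mm <- marginal_type_estimate(chain, seed = 45)
(C <- confusion_matrix(project_labels(H), mm))
#>     predicted
#> true   0  1  2
#>    0 150  0  0
#>    1   0 21  1
#>    2   0  0 18
reconstruction_error(C)
#> [1] 0.025
label_entropy(type_proportions(C))
#> [1] 0.6009679
colMeans(do.call(rbind, lapply(chain$samples, `[[`, "mu")))
#> [1]  0.014 24.310 47.805
```

`triangle_fraction(H) = 1` says every 2-edge closes a projected triangle —
the regime in which neighborhoods are least informative — yet only 1 of the
40 interacting pairs is mistyped ($\epsilon = 0.025$), and the three Poisson
rates are recovered close to the generating values $(0.01, 25, 50)$. The
confusion matrix rows are true types, columns predicted types; a perfect
reconstruction is diagonal.

A command-line interface wrapping the same functions ships in
`inst/cli/hyperinfer` (subcommands `generate`, `observe`, `infer`,
`estimate`, `baseline`, `evaluate`, `experiment`), e.g.

```sh
Rscript inst/cli/hyperinfer generate --kind worst --n-cliques 4 \
    --clique-size 5 --promote-prob 0.19 --seed 1 --out truth.txt
```

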