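---
title: "Bayesian reconstruction of hypergraphs from noisy pairwise counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian reconstruction of hypergraphs from noisy pairwise counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperinfer)
```

## The problem

Many systems are measured only through pairwise signals: counts of
co-occurrences, contacts, conversations, or interaction events between pairs
of units. When some interactions are genuinely higher-order -- three units
interacting as a group -- the pairwise data still only shows the *projection*
of that structure. `hyperinfer` reconstructs a latent structure from a
symmetric matrix of nonnegative integer pairwise counts $X = [x_{ij}]$,
under two competing structural hypotheses:

* a **hypergraph** $H = (V, E, T)$ with 2-edges $E$ and 3-edges $T$, and
* a **categorical-edges graph** $G = (V, E_1, E_2)$ with disjoint *weak*
  and *strong* edge sets -- the purely pairwise null model.

Both structures project onto a per-pair interaction type
$\ell_{ij} \in \{0, 1, 2\}$: for the hypergraph, a pair covered by any
3-edge has type 2, a pair connected only by a 2-edge type 1, all others
type 0; for the graph, strong edges are type 2 and weak edges type 1.

## Data model

Counts are conditionally independent Poisson draws whose mean depends only
on the interaction type:
$$P(X \mid \mathcal{S}, \mu) = \prod_{i<j}
  \frac{\mu_{\ell_{ij}}^{x_{ij}}}{x_{ij}!} e^{-\mu_{\ell_{ij}}},
  \qquad \mu = (\mu_0, \mu_1, \mu_2).$$
$\mu_0$ is the background rate of spurious observations for
non-interacting pairs (typically orders of magnitude below $\mu_1$), and
$\mu_1, \mu_2$ the expected counts for weak and strong interactions over
the observation window. Log-factorials are evaluated through the
log-gamma function, so large counts are safe.

## Priors and identifiability

Hyperedges exist independently: 2-edges with probability $q$, 3-edges with
probability $p$ (hypergraph), or strong edges with probability $q_2$
followed by weak edges with probability $q_1$ among the remaining pairs
(graph). Rates get gamma priors and the structure probabilities beta
priors; the package defaults, gamma(shape 1, rate 0.1) and beta(1, 1), are
weakly informative and exposed through `prior_spec()`.

Two identifiability issues shape the sampler:

* **Hidden hyperedges.** The projection is lossy: a 2-edge inside a pair
  covered by a 3-edge, or a 3-edge whose pairs remain covered by others,
  can be removed without changing any label (`hidden_hyperedges()` finds
  them by single-removal recomputation). Such hyperedges are unrecoverable
  in principle; evaluation therefore focuses on interaction types rather
  than raw hyperedge lists.
* **Label switching.** Swapping all labels $0 \leftrightarrow 1$ together
  with $\mu_0 \leftrightarrow \mu_1$ leaves the likelihood unchanged. The
  sampler imposes $\mu_0 < \mu_1$ and $\mu_0 < \mu_2$ for the hypergraph
  model; $\mu_1 < \mu_2$ is *not* imposed there because 3-edges correlate
  pairs and disambiguate the strong class in all but pathological
  configurations. The graph model has no such correlations, so it uses the
  full chain $\mu_0 < \mu_1 < \mu_2$.

## Posterior sampling

`run_chain()` is a Metropolis-within-Gibbs sampler. Each sweep performs

1. a block of single-hyperedge flip proposals (uniformly a pair-flip or a
   triple-flip, then a uniform candidate; for the graph model a uniform
   pair and a uniform different label). Proposals are symmetric, so
   acceptance uses the posterior ratio, evaluated only over the pairs whose
   label changes;
2. a conjugate gamma draw of each $\mu_k$ (shape + type-$k$ count sum,
   rate + type-$k$ pair count), truncated by inverse-CDF sampling so the
   ordering constraints hold against the current values of the other
   rates; a type with no pairs draws from its truncated prior;
3. a conjugate beta draw of the structure probabilities from the hyperedge
   counts.

Defaults are 2000 burn-in sweeps, thinning 10 and 500 retained samples
(the sample size used for all of the package's own summaries), with
$\binom{n}{2} + \binom{n}{3}$ proposals per sweep, capped at
$20\binom{n}{2}$ for $n > 40$ so that large instances stay desk-scale. All
randomness flows through R's RNG: one seed reproduces a chain bit for bit.
Correctness of the whole loop is validated against exhaustive posterior
enumeration on four vertices ($2^{10}$ hypergraphs, $3^6$ labelings),
where every marginal must sit within Monte-Carlo error of the exact value,
and every stored log-posterior re-evaluates exactly from the likelihood
and prior modules.

### Initialization

Chains start from a heuristic fit: a three-component Poisson-mixture EM on
the counts (several data-driven restarts, best likelihood wins; an
empirical quantile split is the fallback) gives rate estimates, and pairs
are classified at the *unweighted* pmf crossings of adjacent components --
the weighted boundary would starve the rare strong class whenever the two
interacting components overlap. The hypergraph start then keeps every
interacting pair as a 2-edge and seeds 3-edges by a greedy local posterior
test over the triangles of the interacting graph: candidates are visited
in decreasing order of the log-posterior gain of "3-edge present, covered
2-edges pruned" versus "pairs fall back on their 2-edges", and added while
the gain over still-uncovered pairs is positive.

Seeding is worth this care because single-flip dynamics are asymmetric in
a way that creates metastability on both sides. A missing 3-edge must
nucleate against already-placed 2-edges through a prior barrier, which is
slow when $\mu_1$ and $\mu_2$ overlap; a wrongly promoted 3-edge becomes
effectively unremovable once the hidden 2-edges beneath it are pruned
(their removal is prior-favored and likelihood-neutral, so it happens
quickly), because removing the 3-edge would then expose its pairs as
non-interacting. The greedy test keeps genuine triangles of strong pairs
and rejects triangles that would cover weak pairs, in both the sparse
("best-case") and clique-heavy ("worst-case") regimes below.

## Estimators and evaluation

From a chain the package derives the maximum a posteriori structure
(`map_estimate()`, best-of-chain with earliest-sample tie-breaking), the
edge-wise structure of hyperedges with marginal probability strictly above
0.5 (`edgewise_estimate()`; for the graph model the three label states are
compared jointly per pair, which keeps the weak and strong sets disjoint),
and the maximum-marginal interaction types (`marginal_type_estimate()`,
per-pair modal label with seeded random tie-breaking).

Evaluation against a planted truth uses the 3x3 confusion matrix $c_{rs}$
and, from it, the relative reconstruction error
$$\epsilon = \frac{c_{10} + c_{12} + c_{20} + c_{21}}
  {c_{10} + c_{11} + c_{12} + c_{20} + c_{21} + c_{22}},$$
the predicted-type proportions $\rho_k$ and their base-3 entropy
$S = -\sum_k \rho_k \log_3 \rho_k$ (1 when the three types are uniformly
represented, 0 when a single type survives -- a cheap detector for a model
that silently drops a class). Posterior-predictive residual sums
$R_k = \sum_{i<j} (x_{ij} - \tilde{x}_{ij})\,\delta_{k,\ell_{ij}}$, with
$\tilde{X}$ regenerated from posterior samples, flag per-type bias in the
fitted rates; both the per-draw mean and the total over draws are
reported. Statistics that are undefined -- $\epsilon$ with no interacting
pairs, the projected-triangle fraction with no 2-edges -- return `NA`
rather than 0, so sweeps over $\mu_1$ cannot silently absorb degenerate
replicates.

## Threshold baseline

The natural non-Bayesian competitor classifies each pair by its count
alone: weak if $x_{ij} \ge t_1$, strong if $x_{ij} \ge t_2$. The optimal
cut points are the intersections of adjacent weighted Poisson components,
$$z(\lambda_1, \psi_1; \lambda_2, \psi_2) =
  \frac{\lambda_2 - \lambda_1 - \ln\psi_2 + \ln\psi_1}
       {\ln\lambda_2 - \ln\lambda_1},$$
with the class proportions as weights (`optimal_thresholds()`,
`threshold_classify()`). Thresholds are kept real-valued and compared with
$\ge$. When no ground truth supplies the class proportions,
`class_priors_from_chain()` estimates them from a posterior chain.

## Planted-structure generators

`generate_best_case()` samples a hypergraph from its prior and removes, in
seeded random order, every 2-edge closing a triangle in the projected
interaction graph $\Delta \cup E$; in the result, neighborhoods identify
3-edges unambiguously and the projected-triangle fraction
$E_\Delta$ (`triangle_fraction()`) is 0. `generate_worst_case()` builds
disjoint cliques of 2-edges and promotes each within-clique triangle to a
3-edge with a given probability, removing the three covered 2-edges (they
would otherwise be hidden and unrecoverable, contaminating evaluation);
every retained 2-edge then closes a triangle, $E_\Delta = 1$, and a pair's
neighborhood carries no information about its type.
`generate_sbm()` superimposes community structure: 2-edges by a
community-pair probability matrix, 3-edges by within- and
between-community probabilities.

These generators emulate the study conditions exactly -- independent
hyperedge placement and Poisson counts. They do *not* emulate degree
heterogeneity, overdispersed or correlated measurements, or hyperedges
beyond size 3, so green tests here say nothing about data violating those
assumptions; the data model is explicitly the simplest member of its
family and should be rechecked against any empirical dataset's count
histogram before use.

## Study designs used by the package's own checks

The test-suite and the acceptance script rerun scaled versions of the
package's reference experiments, chosen once as follows:

* **Recovery** (best case): $n = 50$ with $q = 0.076$, $p = 0.00068$ --
  four times the reference densities used at $n = 100$, keeping expected
  hyperedge counts comparable -- observed with $\mu = (0.01, 40, 50)$;
  10 replicates, 500 retained samples each, burn-in 300. Tolerances on the
  recovered rates are 10% relative, floored at three standard errors of
  the replicate median; the floor matters only for $\mu_0$, whose
  posterior spread (about a dozen expected events across ~1100 pairs)
  exceeds 10% of its value by design of the sparse regime.
* **Model comparison**: the same best-case design and the worst-case
  design (20 isolated 5-cliques, promotion probability 0.19, $n = 100$)
  at $\mu = (0.01, 25, 50)$. The hypergraph model must do at least as well
  as the categorical-edges model on the best case, and its advantage must
  shrink or reverse on the worst case, as medians over 10 replicates.
* **Sampler validation**: $n = 4$ instances against exhaustive
  enumeration, with $10^4$ retained samples and batch-means standard
  errors.

## Known limitations

* Hyperedges are limited to size 3; larger interactions must be broken
  into triples upstream.
* The observation model is equidispersed Poisson; bursty measurement
  processes will bias the rates.
* The MAP estimator is the best retained sample, not a separate optimizer;
  with short chains it inherits their variance.
* In regimes where $\mu_1$ and $\mu_2$ overlap substantially, single-flip
  chains mix slowly between "merged" and "separated" explanations of the
  strong class; initialization mitigates this, but very short chains can
  still understate the number of 3-edges on individual replicates.
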