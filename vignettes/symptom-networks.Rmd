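---
title: "Methods: estimating and validating symptom networks from ordinal questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and validating symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The analysis

The package analyses cross-sectional mental health questionnaire data in
which each of 40 symptoms is scored 0–3 (higher = more severe). Thirty-six
items form six clusters — somatization (7 items), cognitive function (5),
negative affect (10), interpersonal communication (4), cognitive processes
(7) and social adaptation (3) — and four symptoms (sleep disturbance,
loneliness, sadness, anger) stand alone. Two weighted undirected networks
are estimated: a 40-node single-symptom network and a 10-node network over
the six cluster sum composites plus the four standalone items. Edge weights
are Spearman rank correlations of the node scores; centrality (strength,
closeness, betweenness) identifies the symptoms whose associations
structure the network.

The networks are descriptive, contemporaneous association models. They
assume complete cases (incomplete records are removed listwise), ordinal
scores whose monotone association is meaningful (Spearman is invariant to
any strictly increasing rescoring of an item, a property the test suite
checks directly), and no causal or longitudinal interpretation.

## Scoring conventions

Several reporting conventions are not forced by the data and had to be
fixed; each is chosen to reproduce the verifiable worked examples in the
packaged reference table (`reference_marginals()`):

* **Prevalence threshold.** A symptom counts as present when its score is
  ≥ 1. This is the only rule consistent with the reference arithmetic
  (e.g. a count of 358 of 503 printing as 71.2%).
* **Cluster composite.** The per-participant *sum* of member-item scores.
  Cluster severity means in the reference table exceed the per-item maximum
  of 3, which rules out a per-item mean.
* **Cluster prevalence.** A cluster is present when any member item is ≥ 1.
* **Standard deviations.** Sample-based (denominator N − 1) throughout.
* **Rounding.** Printed percentages use round-half-away-from-zero to one
  decimal (`round_half_away()`); base R's banker's rounding disagrees on
  exact halves.
* **Cronbach's α.** `k/(k−1) · (1 − Σ item variances / variance of sum)`,
  undefined (an error) when the composite has zero variance.

Two rows of the reference table do not reproduce from their own printed
counts at N = 503 (one item and one cluster percentage, each 0.2 points
off); the package always reports computed percentages, and no validation
quantity depends on those rows.

## Network and centrality choices

* **All edges are kept.** Plain pairwise Spearman estimation, no
  regularization, no significance filter; `min_abs_weight` (default 0) is
  available but off. Rendering may suppress weak edges for legibility
  (`display_threshold` in `plot()`), but estimation and display are
  deliberately separate.
* **Distances.** Shortest-path centralities need a length for an edge of
  weight r; the package uses d = 1/|r|, the dominant convention for
  correlation networks: stronger association = shorter distance, with d ≥ 1
  since |r| ≤ 1. A zero weight means no edge.
* **Absolute weights for strength.** Strength sums |r|, keeping it monotone
  in association magnitude whatever the sign mix.
* **Standardization.** Reported centralities lie in [0, 1]. Two modes are
  implemented because published practice is ambiguous — reported values for
  one network can only arise from dividing each index by its observed
  maximum (top node exactly 1), while values for another are consistent
  with a theoretical-maximum scaling (r_S = strength/(n−1); closeness and
  betweenness are already bounded by 1 under the conventions above). The
  default is `"theoretical-max"`; every output records the mode used.
* **Ties.** Betweenness gives fractional credit across tied geodesics
  (Brandes accounting). Edge rankings and consensus rankings break ties
  lexicographically by node ID so output is deterministic.
* **Disconnection.** Closeness is component-penalized by
  (n_reachable − 1)/(n − 1), keeping it in [0, 1] without dropping nodes;
  an isolated node scores 0. Constant node columns (impossible in real
  complete data, possible in simulation) have undefined rank correlations
  and are dropped with a warning (or rejected, per `constant = "error"`).

Shortest paths and betweenness are computed by igraph; the test suite
verifies strength, closeness and betweenness against independent
exhaustive-enumeration oracles (Floyd–Warshall distances and full
simple-path enumeration) on dozens of seeded random graphs with up to 8
nodes, at tolerance 1e−9, and the Spearman matrix against a from-scratch
mid-rank oracle at 1e−12.

## The synthetic-data generator

No raw participant data are distributed with the reference table, so the
generator is the package's test bed. It is a Gaussian copula: item i's
score is obtained by thresholding a latent standard normal at the quantiles
`qnorm(p0)`, `qnorm(p0+p1)`, `qnorm(p0+p1+p2)`, and the latent vector is
multivariate normal with a specified correlation matrix. Marginals and
association are therefore independently controlled, which is exactly what
validation needs: marginals calibrated to the published prevalence/severity
table, association set by design.

`marginal_to_categories()` inverts a (prevalence, mean severity) target
into four category probabilities. Prevalence fixes p0 and the mean fixes
one more moment, leaving one free degree of freedom; the package resolves
it by allocating the positive mass in geometric proportion
p1 : p2 : p3 = w : w² : w³ and solving the mean constraint for w. The
allocation is deterministic, smooth in the target, and feasible for every
target with prev/100 ≤ mean ≤ 3·prev/100; at the feasibility boundaries
(and as a numerical fallback) the mass collapses to the implied one- or
two-point distribution on {1, 3}.

`calibrate_spec()` builds the default study-shaped generator: 503
participants, item marginals from the packaged reference table, and a
block-structured latent correlation — 0.65 within a cluster, 0.35 between
— chosen once as a realistic dense positive regime: it yields
uniformly positive symptom networks of large density and subscale α above
0.85 for the larger clusters, the qualitative features reported for the
study population. `plant_hub()` overwrites this with an exchangeable
background (default 0.2) plus one hub item correlated (default 0.7) with
all others; such planted matrices are often slightly indefinite, and are
then projected to the nearest positive-semidefinite correlation matrix
(negative eigenvalues clipped, diagonal renormalized) with a warning that
reports the Frobenius distance moved.

What the generator does *not* emulate: polychoric-style measurement models,
item-level missingness mechanisms (missingness is planted directly where
tests need it), longitudinal dynamics, demographic covariates, and the
study's actual inter-item correlation matrix, which was never published.
Passing recovery tests therefore show that the estimator recovers structure
from data *of the assumed form*, not that the published edge weights or
centrality values are reproduced — those depend on the undeposited raw
data and are treated as reference-only.

## Reproducibility and numerics

Each `generate_responses()` call seeds a local RNG and restores the
caller's state, so a `copula_spec` (including its seed) maps to a
byte-identical response matrix. The latent square root uses a symmetric
eigendecomposition (stable for the 40 × 40 matrices involved, tolerant of
semidefinite planted designs). `run_pipeline()` embeds the seed and an MD5
hash of the run configuration in every artifact and writes numeric cells
with 17 significant digits, so edge lists and GraphML files round-trip the
weight matrix exactly and reruns are byte-identical.

The Fruchterman–Reingold layout is hand-written so that its
parameterization is explicit and seeded: with k = sqrt(area/n), repulsion
k²/d between all pairs, attraction w·d²/k along edges (weights enter
linearly — the simplest weighted variant that pulls strongly correlated
nodes centerward), 500 iterations by default, a linearly cooling step cap,
and final isotropic rescaling into [−1, 1]² (isotropic so the layout's
shape, and hence the multiset of pairwise distances, is preserved —
rotating the initial placement rotates the result). Figures are
qualitative; no validation quantity depends on coordinates.

## Problem sizes used in validation

The suite exercises marginal fidelity at n = 50,000 (tolerance ±0.01 per
category), association monotonicity on a latent grid {0, 0.2, 0.4, 0.6,
0.8} at n = 20,000, a Monte-Carlo association oracle with 10⁶ independent
draws (±0.03), strength-ratio recovery at n = 50,000, hub recovery at
n = 2,000 (10 items, 20 replicates, ≥ 18 required) and at the study scale
n = 503 (40 items, 20 replicates, top-3 consensus in ≥ 90%). These sizes
were chosen to make sampling noise negligible relative to each tolerance
while keeping the default test run fast.

## Known limitations

* Cross-sectional Spearman networks support no causal or directional
  claims; centrality is descriptive.
* Edge stability and centrality stability are not bootstrapped;
  regularized (e.g. graphical-lasso) networks are out of scope.
* The observed/theoretical standardization ambiguity cannot be resolved
  from published values alone; both modes are provided and labeled.
* Ordinal Spearman correlations are attenuated relative to the latent
  association (visible in `simulate()` round-trips, which are close but
  slightly shrunk); the package works on the observed-score scale
  throughout and does not attempt latent-scale correction.
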