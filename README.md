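# symptomnet

Cross-sectional **symptom network analysis** for ordinal mental health
questionnaire data, built for studies of persons living with HIV (PLWH) and
similar populations in which many co-occurring symptoms are assessed with a
multi-subscale instrument.

The package implements the complete pipeline for a 40-item, six-cluster
instrument (items scored 0–3):

1. **Scoring** — listwise exclusion of incomplete records; per-item
   prevalence (share of participants scoring ≥ 1) and severity (mean ± SD);
   cluster sum composites; Cronbach's α per subscale.
2. **Network estimation** — weighted undirected networks whose nodes are
   single symptoms (40 nodes) or symptom clusters plus standalone symptoms
   (10 nodes), with edge weights r given by the Spearman rank correlation of
   the node scores. No thresholding is applied by default.
3. **Centrality** — strength r_S (sum of absolute incident weights),
   closeness r_C (inverse total shortest-path distance under the d = 1/|r|
   length convention, penalized for disconnection) and betweenness r_B
   (Brandes shortest-path betweenness with fractional credit for tied
   geodesics, normalized by (n−1)(n−2)/2), each standardized to [0, 1]
   under either a theoretical-max or an observed-max rule.
4. **Layout** — a seeded weighted Fruchterman–Reingold placement that pulls
   strongly correlated nodes toward the center, for figure-style rendering.
5. **Synthetic data** — a Gaussian-copula generator for correlated 0–3
   ordinal responses with exactly specified per-item marginals
   (calibratable to published prevalence/severity tables) and a
   configurable latent correlation structure, including planted-hub designs
   for recovery experiments. The raw study data behind the packaged
   reference table were never deposited, so every stage of the pipeline is
   validated on this generator instead.

## Model in brief

For node scores \(X_i\), the network weight is
\(r_{ij} = \mathrm{cor}_{\text{Spearman}}(X_i, X_j)\) (Pearson correlation of
mid-ranks). Centrality uses

- strength: \(s_i = \sum_{j \ne i} |r_{ij}|\), standardized as
  \(r_S = s_i/(n-1)\) (theoretical max) or \(s_i/\max_j s_j\) (observed max);
- distance: \(d_{ij} = 1/|r_{ij}|\) (no edge when \(r_{ij}=0\));
- closeness: \(c_i = \frac{n_r}{\sum_{j} d_{ij}} \cdot \frac{n_r}{n-1}\)
  over the \(n_r\) reachable nodes;
- betweenness: \(b_i = \frac{2}{(n-1)(n-2)} \sum_{s<t}
  \sigma_{st}(i)/\sigma_{st}\).

The generator thresholds a latent multivariate normal vector at the
standard-normal quantiles of each item's cumulative category probabilities,
so marginals and association structure are controlled independently.

## Worked example

```r
library(symptomnet)

# a synthetic cohort calibrated to the packaged reference marginals
spec      <- calibrate_spec(n_participants = 503, seed = 42)
responses <- generate_responses(spec)

report <- run_pipeline(responses, seed = 42)
report
#> Symptom network analysis report
#>   retained participants: 503 (excluded 0, 0.0%)
#>   networks: 40-node symptom, 10-node cluster (mode: theoretical-max)
#>   top consensus nodes (symptom): nervous, future_uncertainty, weakness
#>   top consensus nodes (cluster): somatization, cognitive_function, negative_affect

report$top_edges$symptom
#>               node_a             node_b    r
#> 1 future_uncertainty     low_confidence 0.60
#> 2            nervous             afraid 0.59
#> 3 future_uncertainty future_discouraged 0.59
```

The report lists, for each network, the strongest edges (largest |r|), a
full centrality table and a consensus ranking (mean of the three per-index
ranks; rank 1 = most central). `plot(report$networks$cluster,
centrality_report = report$centrality$cluster)` draws the force-directed
figure with node size proportional to r_S and edge width proportional to
|r|. With `run_pipeline(..., out_dir = "out")` every artifact (summary
table, edge lists, GraphML, centrality tables, layouts, JSON report) is
written with the seed and a configuration hash embedded, and reruns are
byte-identical.

The synthetic cohort reproduces the *structure* the estimator assumes —
dense positive correlations, high subscale α, calibrated marginals — but
not the specific published edge weights or centrality values, which depend
on the undeposited raw data.

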