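Package: symptomnet
Title: Symptom Network Analysis for Ordinal Mental Health Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation and description of cross-sectional symptom networks
    from ordinal (0-3) mental health questionnaire data. Implements scoring
    of a 40-item, six-cluster instrument (prevalence, severity, sum
    composites, Cronbach's alpha), Spearman rank-correlation networks at the
    single-symptom and symptom-cluster level, strength, closeness and
    betweenness centrality with explicit 0-1 standardization, a weighted
    Fruchterman-Reingold layout for figure-style rendering, and a Gaussian
    copula generator for correlated ordinal responses so that every stage of
    the pipeline can be exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
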