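Package: trajcluster
Title: Temporal State-Sequence Clustering of Pre-Ventilation Health
    Trajectories
Version: 0.1.0
Authors@R: person("trajcluster", "developers", role = c("aut", "cre"),
    email = "maintainers@trajcluster.dev")
Description: Clusters categorical daily health-event sequences from
    claims-style data using a two-stage medoid procedure: per-patient
    trajectories over the year before an index therapy (home non-invasive
    ventilation in COPD) are compressed to patient-medoids by K-means on
    trajectory meta-features, then grouped by Ward agglomerative clustering
    on the Hamming distance matrix with member-count weights and validated
    with the silhouette index.  Includes a synthetic claims-data generator
    with four trajectory archetypes and ordered post-index mortality,
    rule-table cohort selection with attrition reporting, stratified cluster
    profiling (chi-square, one-way ANOVA, Charlson categories), and survival
    comparison (Kaplan-Meier, log-rank, Cox proportional hazards)
    implemented from the defining formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
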