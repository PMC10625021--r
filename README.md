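# trajcluster

Temporal state-sequence clustering of health trajectories before the
initiation of home non-invasive ventilation (NIV) in COPD.

## What this package does, and for whom

In severe COPD, home NIV is prescribed at very different points in the
disease course: some patients start it in ambulatory settings with no
prior hospitalisation, others after repeated severe exacerbations.
`trajcluster` is for epidemiologists and biostatisticians who want to
characterise that heterogeneity from claims-style data: per-patient event
calendars (hospitalisation episodes and outpatient point events) in the
365 days before the first NIV delivery, plus covariates and post-index
vital status.

The package implements the full analysis pipeline as reusable, tested
components:

1. **Cohort selection** — configurable inclusion/exclusion rule tables
   (age at index, incident status over a 5-year lookback, COPD
   qualification, exclusion conditions) with a deterministic attrition
   table.
2. **Trajectory encoding** — each patient becomes a categorical daily
   state sequence `x_i ∈ {0,1,2,3}^365` (none < COPD-exacerbation stay <
   cardiology/respiratory stay < ICU stay; highest-priority state wins on
   overlapping stays; half-open day intervals; day 0 excluded).
3. **Medoid compression** — K-means on standardised trajectory
   meta-features (days, episodes and recency per state), then each
   partition is represented by its *patient-medoid*: the member sequence
   minimising the summed Hamming distance to the partition. Per-patient
   homogeneity is `100·(1 − H(x_i, m_{a(i)})/T)`.
4. **Hierarchical clustering** — Ward agglomeration on the medoid Hamming
   matrix via the Lance–Williams recurrence with member counts as
   observation weights, deterministic tie-breaks, silhouette validation on
   weighted medoids, severity-ordered labels (mean exacerbation episodes,
   ties by hospitalised days), and the member-count-expanded raster for
   index plots.
5. **Cluster profiling** — stratified medians/IQRs and counts/percentages
   with Pearson chi-square and one-way ANOVA tests, Charlson comorbidity
   categories (0, 1–2, 3–4, ≥5).
6. **Survival** — Kaplan–Meier product-limit curves per cluster, global
   and pairwise log-rank tests, and multivariable Cox regression (Breslow
   or Efron ties, Newton–Raphson with step-halving), all implemented from
   the defining formulas and tested against the `survival` package as an
   independent oracle.
7. **Synthetic data** — a claims-data generator with four trajectory
   archetypes (ambulatory/single-stay; ≥2 exacerbation stays in the last
   6 months; stays spread over the year; several long-lasting stays) and
   archetype-ordered exponential post-index mortality, so the whole
   pipeline is testable without any restricted data.

## Worked example

```r
library(trajcluster)

cohort  <- generate_cohort(generator_config(n_patients = 2000, rng_seed = 42))
seqs    <- encode_cohort(cohort$events, cohort$covariates$patient_id)
medoids <- compress_sequences(seqs, k = 100, rng_seed = 42)
medoids
#> medoid_set: 100 medoids for 2000 patients; mean homogeneity 97.0 (sd 4.0)

model <- ward_cluster(hamming_matrix(medoids$medoids),
                      medoids$member_counts, C = 4)
model <- order_by_severity(model, seqs, medoids$assignment)
model
#> traj_clusters: 100 medoids cut into 4 clusters
#> patients per cluster: 1320, 257, 404, 19
#> weighted mean silhouette: 0.531

labels <- model$labels[medoids$assignment]
adjusted_rand_index(labels, cohort$truth$archetype)
#> [1] 0.945
```

Mean homogeneity 97 means the average patient differs from its
representing medoid on ~3% of the 365 days; the cluster sizes reproduce
the generator's 66/12/21/1% archetype mixture; ARI 0.94 says the
recovered partition almost coincides with the generating labels.

```r
rec <- survival_records(cohort$covariates, labels)
sapply(1:4, function(cc) { s <- rec[rec$cluster == cc, ]
                           km_surv_at(km_fit(s$time, s$event), 365) })
#> [1] 0.908 0.782 0.703 0.316      # one-year survival, cluster 1..4

lr <- log_rank(rec$time, rec$event, rec$cluster)
#> global log-rank: chi2 = 335.1, df = 3, p = 2.5e-72

X   <- model.matrix(~ age + sex + charlson + cluster, rec)[, -1]
fit <- cox_fit(rec$time, rec$event, X)
fit$coefficients[5:7, c("term", "hr", "ci_lower", "ci_upper")]
#>      term    hr ci_lower ci_upper
#>  cluster2  2.31     1.78     2.99
#>  cluster3  4.04     3.31     4.94
#>  cluster4 16.30     9.97    26.65
```

Survival decreases monotonically from cluster 1 to cluster 4 and the Cox
hazard ratios recover the generator's hazard ordering.

## Pipeline and command line

`run_pipeline(run_config(out_dir = "...", n_patients = 5000))` runs
simulate → select → encode → compress → cluster → profile → survive and
writes every intermediate artifact as delimited text plus a JSON manifest
(seed, config hash, per-stage rows and timings). The same stages are
available from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "trajcluster.R", package = "trajcluster"))')
Rscript "$CLI" run      --n 5000 --k 100 --n-clusters 4 --seed 1 --out out/
Rscript "$CLI" simulate --n 5000 --seed 1 --out out/
Rscript "$CLI" compress --sequences out/sequences.tsv --k 100 --seed 1 --out out/
```

## Package layout

- `R/` — one file per pipeline stage (`synthetic_data.R`,
  `cohort_selection.R`, `trajectory_encoding.R`, `medoid_compression.R`,
  `tak_clustering.R`, `cluster_profiling.R`, `survival.R`, `pipeline.R`).
- `vignettes/trajectory-clustering.Rmd` — the methods vignette: model,
  assumptions, parameter choices, what the generator does and does not
  emulate, numerical decisions, limitations.
- `tests/testthat/` — unit and property tests per module with brute-force
  oracles, plus `test-acceptance.R` (one block per acceptance criterion).
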