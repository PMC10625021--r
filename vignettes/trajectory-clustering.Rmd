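---
title: "Clustering pre-ventilation health trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering pre-ventilation health trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcluster)
```

## The problem and the model

Home non-invasive ventilation (NIV) in COPD is initiated at very
different points of the disease course, and the year of healthcare use
preceding the first delivery carries the signature of that heterogeneity.
This package treats each patient's pre-index year as a categorical daily
state sequence and clusters those sequences in two stages, a procedure
known in the claims-analytics literature as TAK (time-sequence analysis
through K-clustering) with patient-medoids:

1. Each patient `i` is a vector `x_i` in `{0,...,S}^T` (default `T = 365`
   days, `S = 3` hospitalisation states). Day `t` holds the
   highest-priority state among the stays covering it: ICU (3) over
   cardiology/respiratory (2) over COPD-exacerbation stay (1) over
   nothing (0). Only the three hospitalisation event types enter the
   sequence; point events (consultations, tests, oxygen start) feed the
   descriptive profiling instead.
2. **Compression.** K-means (Euclidean, on standardised meta-features:
   per state, total days, number of episodes, day of last occurrence)
   partitions the cohort into `K` groups; each group is replaced by its
   *patient-medoid*, the member sequence minimising the summed Hamming
   distance to the group. This makes the subsequent `O(K^2)` distance
   matrix tractable and is faithful at the level of the homogeneity
   score, `100 (1 - H(x_i, m_{a(i)}) / T)`, whose cohort mean should stay
   well above 90.
3. **Clustering.** Ward agglomeration on the `K x K` Hamming matrix via
   the Lance-Williams recurrence, with each medoid weighted by the number
   of patients it represents, cut into `C` clusters (default 4), labels
   ordered from least to most severe, silhouette index reported, and the
   raster expanded back to patient rows for index plots.
4. **Downstream comparison.** Stratified descriptive tables
   (chi-square / one-way ANOVA), and post-index survival by cluster
   (Kaplan-Meier, log-rank, multivariable Cox).

### Assumptions worth stating

- *Hamming geometry.* Two trajectories are close when they are in the
  same state on the same calendar days (aligned on the index). The metric
  has no notion of "almost the same time": a 10-day stay shifted by 10
  days is as far from the original as no stay at all. Archetypes are
  therefore discoverable only insofar as they are *temporal templates* --
  this drives both the generator design and the interpretation of real
  results.
- *Ward on a non-Euclidean matrix.* Hamming distances are not squared
  Euclidean distances, so Ward's variance interpretation is approximate.
  We apply the Lance-Williams update on squared distances, the standard
  practice; with unit weights the tree equals `hclust(d, "ward.D2")`.
- *Member-count weighting.* The paper-level object of interest is the
  patient, not the medoid, so member counts enter the linkage (and the
  silhouette) as observation weights. An unweighted mode is available by
  passing `member_counts = NULL`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_days` (T) | 365 | days | "the year before initiation"; configurable because a calendar-month reading would differ by a few days |
| state priority | ICU > cardio/resp > exacerbation | -- | most acute state wins on overlap; configurable via `state_alphabet()` |
| `k` (medoids) | 100 at n = 5000 (3000 at population scale) | count | chosen so mean homogeneity stays >= 90; `compress_sequences()` is cheap enough to sweep K |
| `C` (clusters) | 4 | count | a clinical-relevance choice; a silhouette-vs-C sweep supports but does not dictate it |
| `n_init` | 5 | restarts | best-inertia K-means restart count |
| Cox ties | Breslow | -- | simplest defensible choice; Efron available |
| Charlson weights | config table | -- | the scoring inputs are institution-specific; classic integer weights for the generator's simplified flags by default |

## What the synthetic generator emulates -- and what it does not

`generate_cohort()` draws from a four-archetype mixture
(66/12/21/1% by default):

1. **Archetype 1** -- NIV in ambulatory settings (31.7% of the archetype,
   making the ambulatory subgroup ~21% of the cohort) or after a single
   stay shortly before the index.
2. **Archetype 2** -- at least two exacerbation stays in the final six
   months (enforced as an invariant).
3. **Archetype 3** -- stays spread across the whole year.
4. **Archetype 4** -- several long-lasting stays (log-normal median 22
   days; always above the one-week threshold that defines a
   long-lasting exacerbation).

Episode *timing* is generated from archetype-specific slots with
Gaussian jitter (sd 3-5 days), not from a homogeneous process. This is a
deliberate design decision, decided once and frozen: with fully
independent uniform episode timing, the within-archetype Hamming spread
exceeds each archetype's distance to the empty sequence, the empty
trajectory becomes everyone's nearest neighbour, and *no* clustering of
any kind can recover the mixture (we measured adjusted Rand indices of
0.1-0.2 in that world). A recoverable world -- which the end-to-end
acceptance property presupposes -- must encode archetypes as temporal
templates; the jitter scale is the smallest change that makes that true,
and it produces rasters with the contiguous within-cluster blocks that
real index plots of this kind show. Episode-duration medians
(12/12/10/22 days by archetype) and the comorbidity, age, sex and
prescriber margins follow the published stratified tables of the cohort
being emulated.

Mortality is exponential post-index with archetype hazards
0.08/0.20/0.35/1.20 per year and administrative censoring at 730 days:
enough to order one-year mortality 1 < 2 < 3 < 4 strongly, which is the
qualitative property the survival stage must reproduce.

What the generator does **not** emulate: real diagnosis coding (a single
`copd_drug` marker stands in for the ICD-10/drug qualification
algorithm), seasonal or calendar effects, correlated comorbidity
structure, competing risks, care-pathway feedback (e.g. oxygen start
altering subsequent hospitalisation risk), and the long right tail of
within-archetype trajectory diversity in real claims. A green
parameter-recovery test therefore establishes that the pipeline's
machinery is correct and that crisp temporal archetypes are recoverable
at realistic sizes -- it does not establish that four clusters is the
right description of any real cohort, nor that real-world homogeneity
would reach the values seen here.

## Numerical decisions

- **Homogeneity formula.** The score is reported as a percentage but has
  no published definition; we use the natural [0, 100] normalisation of
  Hamming similarity.
- **Tie-breaking.** Ward merges break minimum-cost ties (tolerance
  1e-12) by the lexicographically smallest pair of original leaf
  indices; K-means assignment ties go to the lowest centroid index;
  the within-partition medoid is the first minimiser. Runs are therefore
  reproducible bit-for-bit given seeds.
- **Empty K-means clusters** are re-seeded from the point farthest from
  its centre; if feature collisions still leave empty partitions (two
  distinct sequences can share meta-features), multi-sequence partitions
  are split deterministically so every medoid has >= 1 member.
- **`K` = number of distinct sequences** bypasses K-means entirely and
  returns the identity compression (mean homogeneity exactly 100), the
  boundary case the feature map cannot otherwise guarantee.
- **Percentages** are displayed with half-up rounding (base R's
  round-half-even does not match how claims tables are printed); full
  precision is kept alongside.
- **Profiling with empty bins or clusters** keeps the descriptive rows
  but computes the chi-square on the reduced table; if fewer than 2x2
  informative cells remain the test is reported as NA rather than an
  error.
- **Cox fitting** maximises the Breslow/Efron partial likelihood by
  Newton-Raphson with step-halving (plain Newton overshoots on flat
  likelihoods -- observed with a 1% cluster); convergence at max
  |score| < 1e-8 or relative log-likelihood change < 1e-10; divergence
  (|coef| > 20, e.g. true separation) and non-convergence in 50
  iterations are errors, not warnings.
- **Kaplan-Meier ties**: deaths precede censorings at tied times.
- **Day convention**: day 0 is the index and is excluded; intervals are
  half-open `[start, end)`, so a one-day stay covers one day; events are
  clipped to `[-T, 0)`.

## Open design choices and their resolution

- *Window definition* ("the year"): fixed at 365 days, configurable.
- *Exacerbation identification*: the published diagnosis-position
  algorithm is not reproducible from the main text; cohort selection and
  encoding therefore work on configurable event-type sets, making the
  qualification rule swappable without touching the pipeline.
- *Same-day index and exclusion marker*: the patient is excluded
  (conservative reading; flagged, not asserted as the source study's
  intent).
- *Meta-feature list and standardisation*: unstated in the source;
  we standardise and include episode counts and recency so temporally
  distinct trajectories separate; a days-only mode is provided.
- *Silhouette target objects*: computed on member-count-weighted medoids
  (equivalent to patients under the compression assumption); the
  unweighted medoid-level value is available by dropping the weights.
- *Log-rank separation*: the pairwise p <= 1e-4 property is a statement
  about the generator's archetype hazards; on fitted clusters,
  misclassification between adjacent clusters dilutes the worst pair by
  a few orders of magnitude, so both quantities are reported.

## Limitations

- The Hamming metric ignores near-misses in time; optimal-matching or
  soft-time-warping distances are out of scope.
- Single-channel sequences only: overlapping stays are resolved by
  priority, not modelled jointly.
- No multiple-testing correction by default in profiling (matching the
  descriptive-table convention of the field); Benjamini-Hochberg is one
  argument away.
- Cox covariates are entered as given (age linear by default); no
  time-varying covariates, frailty or competing risks.
- At small cohort sizes the 1% archetype can contain a handful of
  patients; survival comparison is then unstable (and the Cox MLE may
  genuinely not exist). The pipeline aborts rather than silently
  reporting such fits; desk-scale analyses should use n >= 800.
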