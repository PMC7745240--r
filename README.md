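# trajresp

Longitudinal trajectory clustering of antipsychotic treatment response.

## What this is for

Clinical trials in schizophrenia usually score outcome with the PANSS
(Positive and Negative Syndrome Scale) and dichotomise it: a patient is a
"responder" if their symptom reduction at week 6 reaches 50%. That one-bit
summary hides the *course* of response. trajresp takes the longitudinal view:
it converts the PANSS totals at weeks 0/2/4/6 into floor-corrected percent
reductions, clusters the per-patient reduction trajectories into homogeneous
response subgroups with a from-scratch multi-restart k-means engine, selects
the number of trajectories with the Calinski–Harabasz index, and quantifies
where the trajectory classification and the 50%-threshold rule disagree —
overall, per drug (seven antipsychotic arms), and split by first-episode vs
relapse status.

It is aimed at biostatisticians and psychiatry trialists who want a
reproducible, testable implementation of this analysis, including a synthetic
trial-cohort generator (the original trial data are not public) so every
stage can be exercised end to end.

## The core quantities

Corrected percent reduction of the PANSS total (the total's floor is 30, so
raw percent change cannot reach 100):

```
pct(w) = 100 × (PANSS_0 − PANSS_w) / (PANSS_0 − 30)
```

Each patient is the 3-vector `(pct(2), pct(4), pct(6))`. Lloyd's k-means with
20 random-assignment restarts per k minimises the within-cluster sum of
squares; the cluster count k ∈ {2,…,6} maximises the Calinski–Harabasz index

```
CH = [tr(B)/(k−1)] / [tr(W)/(n−k)]
```

(between- over within-cluster scatter, each per degree of freedom). The
cluster with the larger week-6 centroid is the *high* (better-response)
trajectory. The threshold rule classifies `pct(6) ≥ 50` as responder;
`compare_responses()` cross-tabulates the two classifications, tests the
composition ratio with an uncorrected Pearson chi-squared, and runs
FDR-adjusted (Benjamini–Hochberg) pairwise Fisher tests between drug arms.

## Worked example

```r
library(trajresp)
library(dplyr)

cohort <- generate_cohort(cohort_config(n_patients = 600, seed = 42))
prep   <- preprocess_panss(cohort, seed = 1)
prep
#> <panss_prep> 600 patients, 5 imputation(s)
#>   winsorized cells: 18 | imputed cells: 189 | dropped floor baselines: 0

sel <- cluster_trajectories(prep$trajectories, seed = 7)
tidy(sel)
#> # A tibble: 5 × 3
#>       k objective ch_index
#>   <int>     <dbl>    <dbl>
#> 1     2   131746.    2110.
#> 2     3   113447.    1271.
#> 3     4    96107.    1035.
#> 4     5    85728.     886.
#> 5     6    77784.     792.
tidy(sel$best)
#> # A tibble: 2 × 6
#>   cluster label  size pct_w2 pct_w4 pct_w6
#>     <int> <chr> <int>  <dbl>  <dbl>  <dbl>
#> 1       1 high    288   35.4   58.9   73.1
#> 2       2 low     312   15.3   27.8   31.4

analysis <- sel$assignments |>
  left_join(prep$trajectories, by = "patient_id") |>
  left_join(select(cohort, patient_id, arm, first_episode), by = "patient_id")
compare_responses(analysis)
#> <response_comparison> n = 600
#>   high trajectory: 48.00% | threshold responders: 48.33% (cutoff 50%, inclusive (>=))
#>   discordant patients: 6
#>   composition chi2 = 0.01 (df 1, p = 0.908)
```

Reading this: the CH index peaks at k = 2, so two response trajectories are
selected. Their centroid curves (35/59/73% vs 15/28/31% reduction at weeks
2/4/6) recover the class curves the generator was configured with. In this
simulated cohort the two classification methods almost coincide (6 discordant
patients of 600); on less cleanly separated data the discordance is the
interesting output. `autoplot(sel)` draws the CH scan and
`autoplot(sel$best, data = prep$trajectories)` the trajectory spaghetti with
centroids; `tidy()`/`glance()`/`augment()` expose everything as tibbles.

`run_pipeline(run_config(...), out_dir)` executes the whole
simulate → preprocess → cluster → compare chain from one (YAML-able)
configuration, writing a byte-reproducible bundle (cohort, trajectories,
model JSON, assignments, comparison JSON, markdown report, provenance per
stage). A thin CLI wrapper lives at `inst/scripts/trajresp`
(`trajresp simulate|run-all|report`).

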