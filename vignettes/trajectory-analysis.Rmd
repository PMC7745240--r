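---
title: "Classifying antipsychotic treatment response by trajectory clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying antipsychotic treatment response by trajectory clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajresp)
library(dplyr)
```

## The problem

Antipsychotic response in schizophrenia is heterogeneous: a single end-point
dichotomy ("responder" = at least a 50% symptom reduction at week 6) collapses
the whole treatment course into one bit and ignores *how* a patient got there.
trajresp implements the alternative: cluster the longitudinal profile of
symptom reduction over the early treatment weeks into homogeneous response
trajectories, then ask where the trajectory view and the threshold view
disagree, overall and per drug.

The symptom instrument is the PANSS (Positive and Negative Syndrome Scale).
Its total score ranges 30–210 because every one of the 30 items scores at
least 1, so a raw percent change can never reach 100%. The package therefore
works on the floor-corrected reduction rate

$$\mathrm{pct}(w) = 100 \times \frac{\mathrm{PANSS}_0 - \mathrm{PANSS}_w}{\mathrm{PANSS}_0 - 30},$$

which is 100 exactly at complete remission. Subscales (positive 7–49,
negative 7–49, general 16–112) can sit at their floor at baseline, so their
reduction rate divides by the raw baseline instead
(`percent_change_subscale()`). A baseline total of exactly 30 makes the
corrected denominator zero; such records are rejected with a warning rather
than patched, since an actively symptomatic trial population cannot sit at
the scale floor.

## The synthetic cohort

The trial data behind this design are not public, so the package ships a
generator whose defaults *are* the study conditions: seven arms randomised
1:1:1:1:1:½:½ (risperidone, olanzapine, quetiapine, aripiprazole,
ziprasidone, then the two first-generation drugs perphenazine and
haloperidol at half weight); two latent response classes with mean corrected
reduction 35.84/60.51/73.58% (high) and 15.16/28.10/31.99% (low) at weeks
2/4/6, mixed 48.9%/51.1%; and 12.62% monotone dropout. Follow-up totals are
generated by *inverting* the corrected percent-change formula around the
class curve, `total_w = baseline − pct/100 × (baseline − 30)`, so the
configured curves are exact in reduction-rate space — the space the
clustering operates in — up to integer rounding of scores.

Where the study conditions are silent we fixed values once, on clinical
plausibility, and did not revisit them:

* baseline total ~ Normal(90, 15) truncated to (30, 210] — a typical acute
  inpatient severity;
* within-class noise sd of 8 percentage points per visit, the separation at
  which the two printed curves are distinct but overlapping
  (week-6 gap 41.6 points ≈ 5σ);
* isolated missed visits at 2% per patient-visit (MCAR), on top of monotone
  dropout;
* 45% first-episode patients; age at onset ~ N(24, 6); doses carried as an
  opaque risperidone-equivalent in 2–8 mg/day.

Subscale scores are a proportional split of each visit total (the subscale
floors 7+7+16 and ceilings 49+49+112 sum exactly to the total bounds, so the
proportional point is always feasible) plus bounded integer jitter with an
exact repair, guaranteeing `total = positive + negative + general` row by
row.

What the generator does *not* emulate: informative (MNAR) dropout — the
trial's dropouts were younger, more often drug-naive and milder, a mechanism
we deliberately do not guess at — nor site effects, titration dynamics or
side-effect-driven discontinuation. Passing tests on this cohort therefore
demonstrate that the pipeline recovers *the structure it assumes*; they are
not evidence about robustness to informative missingness.

```{r cohort}
cohort <- generate_cohort(cohort_config(n_patients = 600, seed = 42))
cohort |> select(patient_id, arm, first_episode, panss_total_w0, panss_total_w6) |> head(4)
```

## Preprocessing: winsorize, impute, transform

Three decisions here were genuinely open and are package policy, documented
rather than inferred:

1. **What gets winsorized, and when.** Scores beyond quartile ± 1.5 × IQR are
   replaced by the 0.01/0.99 quantiles of the same column. We winsorize the
   *raw score columns, per visit, before* the percent-change transform and
   before imputation: an outlying score is a measurement artifact; an
   outlying ratio may just be a small denominator. Quantiles use the
   linear-interpolation convention (`type = 7`) by default; the convention is
   a `preprocess_panss()` argument because the 0.99-quantile replacement
   value depends on it.
2. **Imputation.** Missing follow-up totals are completed by
   chained-equation regression with predictive mean matching (donor pool of
   5 nearest predictions, 20 chained iterations, 5 completed datasets).
   PMM guarantees imputed values are always observed values, hence always
   inside the scale bounds. Baseline is never imputed — a missing baseline is
   an error. Downstream stages use the first completed dataset by default;
   all completed trajectory sets are returned for sensitivity checks. Pooled
   (Rubin's-rules) inference across imputations is out of scope.
3. **Order.** Winsorize → impute → percent change. Imputation regressions
   then see winsorized predictors, and percent changes are computed on
   completed data only.

```{r prep}
prep <- preprocess_panss(cohort, seed = 1)
prep
head(prep$trajectories, 3)
```

## The clustering engine

The engine is a from-scratch multi-restart k-means (Lloyd's algorithm) on the
3-vector of corrected reductions at weeks 2/4/6. Week 0 is identically zero
for everyone and is excluded as uninformative. Numerical and algorithmic
choices:

* **Distance** — plain Euclidean on raw reduction rates. All three
  dimensions share units (percent), so no standardisation is applied.
* **Initialisation** — each patient is assigned uniformly at random to one of
  the k trajectories (re-drawn until every cluster is non-empty), matching
  the "arbitrary initial assignment" formulation; a restart r draws from an
  RNG stream seeded `seed + r`, so fits are reproducible and restarts
  independent. 20 restarts per k is the default; the best (lowest
  within-cluster sum of squares) run wins, ties to the earlier restart.
* **Convergence** — exact assignment fixed point, with a `max_iter = 200`
  safeguard. The objective is non-increasing across update/reassign pairs.
* **Empty clusters** — a cluster emptied by reassignment is re-seeded with
  the point farthest from its current centroid, taking donors only from
  clusters that can spare a member (size ≥ 2), so repair can never cascade
  into emptying another cluster.
* **Degenerate partitions** — a partition with zero within-cluster scatter
  has an infinite Calinski–Harabasz index; it is returned as `Inf` with a
  warning rather than an error, since it is a legitimate "perfect" solution
  on duplicated points.

The number of trajectories is selected by maximising the Calinski–Harabasz
index, `[tr(B)/(k−1)] / [tr(W)/(n−k)]`, over k = 2..6; exact ties break
toward smaller k (parsimony). Whether to cluster raw or standardized rates
was open; raw rates are used for the unit-homogeneity reason above. The
two-cluster solution's clusters are named by the final-week centroid:
larger = `"high"` trajectory, smaller = `"low"`; for k > 2 clusters are
named `cluster_1` (lowest) to `cluster_k`. Final-week ties break by week 4,
then week 2, then cluster index.

```{r cluster}
sel <- cluster_trajectories(prep$trajectories, seed = 7)
tidy(sel)
tidy(sel$best)
```

Shape-respecting distances (Fréchet, dynamic time warping) and parametric
growth-mixture models are explicit non-goals: the point of the partitional
approach is to avoid distributional and shape assumptions.

## Comparing with the 50% threshold

`compare_responses()` contrasts trajectory membership with the conventional
responder dichotomy. The cutoff is inclusive (`pct ≥ 50`) by default — the
definition alternates between "at least 50%" and ">50%" in common usage — and
both the cutoff and the strictness are configurable and echoed in every
output.

Two constructions deserve care:

* The **composition table** compares the *composition ratio* of good/poor
  response under the two methods. Each patient contributes one count per
  method (grand total 2n) and the two rows are tested as independent samples
  with an uncorrected Pearson chi-squared. This is the construction that the
  published composition statistic (χ² = 43.37 on counts 1471/1539 vs
  1726/1284) corresponds to; the statistically conventional paired
  alternative — McNemar on the discordant cells — is provided separately as
  `mcnemar_discordance()` and reported alongside, never silently swapped in.
* The **paired cross-tab** counts the patients the methods classify
  inconsistently (high-trajectory non-responders and low-trajectory
  responders); its off-diagonal sum is the discordance headline.

Per-arm comparisons build 7×2 tables against both classifications, use the
Pearson chi-squared unless any expected count falls below 5 (the either/or
rule needs a criterion; 5 is the textbook one), and run all 21 pairwise 2×2
Fisher tests — on the responder table by default — with Benjamini–Hochberg
adjustment. Note that BH adjustment is a step-up envelope, not an idempotent
map: re-adjusting already-adjusted values generally inflates them, so adjusted
p-values are computed exactly once, from raw p-values.

```{r compare}
analysis <- sel$assignments |>
  left_join(prep$trajectories, by = "patient_id") |>
  left_join(select(cohort, patient_id, arm, first_episode), by = "patient_id")
cmp <- compare_responses(analysis)
cmp
```

## Reproducibility and problem sizes

`run_pipeline()` executes simulate → preprocess → cluster → compare from one
`run_config()` (or its YAML equivalent) and writes a bundle whose every file
is a deterministic function of the configuration: all stage seeds derive from
the master seed by fixed offsets and are recorded in per-stage provenance
JSON, so re-running a config reproduces the bundle byte for byte. The test
suite exercises cohorts of 100–3010 patients; the model-selection recovery
study in the acceptance script uses 100 replicate cohorts of n = 500 at the
default class curves and noise sd 8, and the end-to-end checks run the full
3010-patient pipeline — sizes chosen so the whole battery completes in a few
minutes on one core while keeping Monte-Carlo error well inside the asserted
margins.

## Known limitations

* MCAR missingness only; informative dropout is acknowledged, not modelled.
* Single-dataset imputation mode by default; between-imputation spread is
  available but no pooling rules are applied.
* The composition chi-squared deliberately treats paired classifications as
  independent samples (see above); interpret it as a composition contrast,
  not a paired test.
* Latent classes in the generator are independent of arm and episode status;
  arm- or episode-linked response differences must be injected by the user
  if wanted.
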