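---
title: "Methods: survival-forest risk stratification for 30-day readmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-forest risk stratification for 30-day readmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(readmitrsf)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical decisions
taken where a design was genuinely open. The README shows the user-facing
workflow; here we explain why the pieces are the way they are.

## The modelling problem

The outcome is readmission to inpatient care within 30 days of an index
inpatient discharge, for patients alive and not transferred at discharge.
Predictors are restricted to the 12 months *before* the index discharge:
encounter-type visit counts (emergency, outpatient, inpatient,
pre-admission, recurring), accumulated inpatient length of stay,
chronic-condition burden, total and non-redundant laboratory / medication /
radiology counts, and demographics. The look-back window is half-open,
`(index_date − 365, index_date]` by discharge date, and the index encounter
itself is excluded, so no feature can read post-index information — a
leakage guard the test suite checks by injecting post-index encounters and
asserting the feature matrix is unchanged.

Risk heterogeneity is handled by stratification rather than interaction
terms: four parallel models for the strata defined by (≥1 chronic-disease
diagnosis in look-back) × (≥1 inpatient admission in look-back). The
stratification threshold is one unit in each direction because readmission
risk rises from the first chronic condition and the first prior admission;
pooling the strata into one model is possible but conflates populations
whose hazard scales differ by an order of magnitude.

## Random survival forest

Each stratum model is a bagged ensemble of survival trees grown on
with-replacement bootstrap resamples. At every node a fresh draw of `mtry`
candidate predictors is searched exhaustively: every midpoint between
consecutive distinct observed values is a candidate cut, and the chosen
split maximizes the absolute standardized log-rank statistic between the
two daughters. Ties in the statistic are broken deterministically
(alphabetically lower feature name, then lower cut) so a fit is a pure
function of data and seed.

Numerical conventions in the split statistic:

* risk-set terms with a single sample at risk (`Y_i = 1`) contribute zero to
  the denominator — the `(Y_i − 1)` factor would otherwise divide by zero
  while the `Y_{i1}/Y_i (1 − Y_{i1}/Y_i)` factor is simultaneously zero;
* a candidate with a non-positive denominator, an empty daughter, or no
  events is an *invalid split*, silently skipped rather than an error;
* the split sweep is incremental (prefix sums plus two Fenwick trees over
  the event-time buckets), which makes each candidate cut O(1) after an
  O(log T) per-sample update; the test suite verifies this path against a
  direct brute-force enumeration, and the statistic itself against the
  two-sample log-rank chi-square from the survival package at 1e-8.

Terminal nodes store the Nelson–Aalen cumulative hazard
`H(t) = Σ d_i / Y_i` over their samples. The alternative `−log` Kaplan–Meier
estimator (the textbook identity `H = −log S`) is available via
`chf_method = "neg-log-km"`, but it is not the default: in deep trees many
leaves are fully eventful, their Kaplan–Meier survival reaches exactly zero,
and `−log 0` is not a usable prediction (the implementation floors survival
at 1e-12 in that mode). Nelson–Aalen is the estimator used by standard
random-survival-forest practice and needs no floor.

Trees are grown until a node has fewer than `nodesize_min` samples, no
events, or no valid split. `nodesize_min = 1` (growth to single-sample
purity) is supported; the default is 3, which trades a little purity for
leaf-hazard stability at the cohort sizes the package targets. `mtry`
defaults to `⌈√p⌉`, standard forest practice. The ensemble hazard is the
plain average over trees, evaluated at the scoring horizon `t* = 30` days;
training uses the full observed times (censored at the generator's
follow-up horizon), not the 30-day truncation.

## PPV calibration and tiers

Sub-cohort hazards are not comparable across models, so each model is
calibrated on its held-out calibration cohort: for every observed hazard
value `h`, the raw PPV is the readmission fraction among calibration
samples with `H ≥ h` (the inclusive inequality makes the maximum-`H` sample
well defined). The score is 100 × a monotone version of that curve, read by
left-step interpolation (the score of the largest knot not exceeding `h`,
clamped at the ends) — matching the threshold semantics of PPV.

Raw PPV curves are not monotone in finite samples; the tail subsets behind
the largest hazards hold a handful of patients and their PPVs are noise. We
therefore apply isotonic regression by pool-adjacent-violators, weighted by
the size of each tail subset. One-sided alternatives that keep the top
knots untouched were considered and rejected: a running minimum taken from
the top preserves the top-risk PPV *exactly*, but that value is a single
Bernoulli draw — whenever the largest-`H` calibration sample happens not to
readmit, the running minimum collapses the entire map to zero. Weighted
PAVA is the canonical estimator of a monotone curve and degrades nothing
else; it is hand-implemented (~15 lines) because base `isoreg()` has no
weights.

Tiers are Low (< 30), Intermediate ([30, 70)) and High (≥ 70). The 30/70
thresholds are conventional rather than optimized and are exposed in the
configuration.

## Evaluation

* `bin_rates()`: event fraction in the ten score bins [0,10), …, [90,100]
  (top bin closed so a score of 100 is representable). Empty bins report
  `NA`, never a fabricated 0, and a monotone-regularized column uses the
  same weighted PAVA as the calibration map.
* `km_curve()`: per-tier Kaplan–Meier readmission-free curves at integer
  days 0–30, via `survival::survfit`; events after the horizon count as
  readmission-free within it.
* `c_statistic()`: the binary 30-day AUC in its Mann–Whitney midrank form.
  It is the binary statistic, not Harrell's time-dependent concordance,
  because the downstream decision object is the 30-day label; the
  implementation is the three-line rank formula and is cross-checked
  against an independent ROC package at 1e-10 in the tests.
* `median_time_to_event()`: the first day at which the conditional
  distribution of event times among 30-day readmissions reaches one half,
  read off the curve.

## High-risk phenotype clustering

High-tier encounters are projected onto the top two principal components of
their standardized feature matrix, then clustered by K-means (Lloyd,
seeded random restarts; each `k` additionally warm-starts from the previous
best solution plus its worst-fit point, which makes the TWSS trace provably
non-increasing in `k`). The cluster count is the largest `k` whose TWSS
reduction rate `R_k` exceeds 0.2. That formal rule and the informal
"where `R_k` peaks" heuristic can disagree, so `select_k()` reports both
(`K` and `k_peak`); the formal rule decides.

Two numerical choices matter here:

* **Variance stabilization.** Utilization counts are heavy-tailed with
  multiplicative dispersion: on the raw scale the high-utilization region
  of the projection is far more spread out than the rest, and K-means keeps
  paying for splitting it, inflating the selected `K`. Non-negative
  features are therefore `log1p`-transformed before z-scoring (features
  with negative values — signed or already-centered covariates — are
  z-scored only). `transform = "none"` restores plain z-scoring.
* **Sign convention.** Each component's sign is fixed so its
  largest-magnitude loading is positive, making the projection
  deterministic.

Profiles per cluster report the usual phenotype panels: mean laboratory /
radiology / medication counts, chronic burden, age-group percentages
(summing to 100 within a cluster) and per-condition prevalence, plus the
within-cluster sum of squares, whose total the tests tie back to `TWSS_K`.

## The synthetic cohort generator

No public readmission EHR corpus with the needed structure exists, so the
generator is a first-class, tested module that emulates what the analysis
assumes — and nothing more:

* a 24-month calendar with one index inpatient discharge per patient in
  months 13–24, so every index has a complete 12-month look-back, plus
  encounters planted *before* the window to exercise the date filter;
* a discrete-time geometric readmission hazard per patient,
  `h = logistic(logit(p0) + Σ β z)`, with default `p0 = 0.002`/day and log
  hazard ratios 0.25 per chronic condition, 0.30 per prior inpatient stay,
  0.10 per age bin and 1.5 for planted high-risk archetype membership. The
  defaults put the marginal 30-day event rate in the 20–30% range — higher
  than statewide registry rates, deliberately, so that every stratum and
  tier keeps enough events at desk scale (10,000 discharges) for stable
  calibration and evaluation;
* named extra covariates: any unrecognized name in `effect_log_hr` becomes
  a standard-normal patient column with that log hazard ratio — a zero
  plants a pure-noise feature. This is how the recovery experiments plant
  "10 signal + 40 noise" designs;
* planted high-risk archetypes on a 3 × 2 grid of utilization intensity ×
  chronic burden. The grid is deliberately two-dimensional so the planted
  cluster structure survives a rank-2 PCA, and archetype encounter volumes
  are nearly deterministic around their level: a dispersed shared volume
  factor would dominate the residual within-archetype variance, leave the
  clusters elongated, and keep `R_k` above threshold past the true `K`
  (the reduction rate is scale-free, so only the residual *shape* matters);
* 60-day administrative follow-up (events between day 31 and 60 train the
  survival model but are non-events for the 30-day label), with an optional
  `admin_censor_prob` to inject uniform censoring and exercise the
  censoring-aware paths. The default is complete-case, matching a cohort
  definition whose qualification rules remove deaths and transfers.

What the generator does **not** emulate: coded diagnosis vocabularies
(conditions are opaque flags), laboratory values (only counts),
inter-facility patient movement, seasonal admission patterns, and
missingness. Tests passing on this generator therefore demonstrate that the
pipeline recovers the structures it is told to recover at realistic noise
levels — not that the model transfers to any particular health system.

## Feature selection

`forward_feature_selection()` reproduces the two-round scheme: a
full-feature fit ranks predictors by permutation importance (the increase
in MSE of the calibrated score against the 30-day label when one feature
column is permuted); modelling restarts from the top 10 and adds features
in descending importance in batches of 5; each step refits, recalibrates,
and records sensitivity, specificity and PPV at the High threshold. Those
three numbers need a scalar combiner for a stopping rule, and we use
Youden's index (sensitivity + specificity − 1), stopping after `patience = 2`
consecutive steps without a `tol`-sized improvement and returning the
best-scoring set. Batch size, tolerance and patience are configuration, not
claims about the original procedure, which did not state them.

## Reproducibility and problem sizes

Every stochastic stage draws from a named substream of one run seed
(generation, facility split, per-stratum bootstrap, permutations,
clustering restarts), and the pipeline's JSON artifacts serialize doubles
at 17 significant digits, so a rerun — or a model reloaded from
`model.json` — reproduces scores byte for byte. The test suite runs the
statistical checks at deliberately desk-sized configurations (cohorts of
900–10,000 discharges, forests of 15–100 trees, ten seeded repeats for the
recovery experiments); these sizes are the package's chosen study
conditions and are printed in the tests themselves.

## Known limitations

* One index discharge per patient; repeated within-patient discharges and
  their correlation structure are out of scope (the split is patient-level
  where it matters).
* No competing risks: death after discharge is not modelled, consistent
  with the complete-case generator.
* Importance for strongly correlated features is interpretable only
  jointly: permuting one of two near-duplicate columns sends samples down
  contradictory tree paths, which can *raise* the measured MSE increase for
  each copy even as the two share split usage. The tests document this
  behaviour.
* The PPV score is a tail probability, not an individual event probability;
  reading it as `P(readmit | score = s)` is a (conservative) approximation
  that the calibration-semantics test quantifies.
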