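---
title: "Screening for prediabetes from CGM traces: models, metrics, and the 2-step rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for prediabetes from CGM traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmscreen)
```

## The screening problem

HbA1c at the 5.7 % cut-off is the standard office screen for prediabetes,
but it is a blunt one: because the ADA definition of prediabetes also
admits impaired fasting glucose (IFG, fasting glucose 5.6–6.9 mmol/L) and
impaired glucose tolerance (IGT, 2-hour OGTT glucose 7.8–11.0 mmol/L), a
substantial fraction of prediabetic individuals sit below 5.7 % and are
invisible to the HbA1c rule. Against ADA-derived labels the rule is
perfectly specific by construction — an HbA1c of 5.7 % or more *is* one of
the prediabetes criteria, so a positive can never be ADA-normoglycemic —
but its sensitivity is limited to the subset of prediabetes that expresses
through glycation.

Wearable continuous glucose monitoring (CGM) offers a way to recover some
of the missed cases: prediabetic individuals show visibly larger glycemic
variability over a 1–2 week wear. `cgmscreen` implements that idea as a
tested pipeline:

1. parse and clean flash-CGM exports (warm-up trimming, block merging,
   coverage rules);
2. reduce each trace to a 13-dimensional glycemic-variability feature
   vector;
3. label participants by the ADA criteria from fasting glucose, 2-hour
   OGTT glucose and HbA1c;
4. fit logistic-regression (LR) and RBF-SVM classifiers on nested
   predictor sets, with an optional *2-step* strategy that hard-classifies
   everyone at or above the HbA1c threshold and lets the model rank only
   the remainder;
5. evaluate by repeated random-subsampling validation.

Because no patient-level cohort is distributed, the package ships a
calibrated synthetic cohort generator; every claim the test suite makes is
made against that generator, and the section on its limitations below
spells out what that does and does not establish.

## Trace preprocessing

A `glucose_trace` is an irregular time series of mmol/L readings at
roughly 15-minute spacing, partitioned into sensor blocks (one block per
sensor wear). Three rules govern preprocessing:

* **Warm-up trimming.** The first 24 h of every block are discarded —
  first-day flash-sensor readings run systematically low. Trimming is
  idempotent and applied per block, so a participant who wore two sensors
  loses 48 h in total (`merge_blocks()`).
* **No interpolation.** All statistics are duration-weighted on the native
  irregular grid. Reading *i* carries weight
  `min(t[i+1] − t[i], gap_cap)` hours; the last reading carries the median
  interval. The gap cap defaults to 8 h, the on-sensor memory of a flash
  sensor — an interval longer than that is true data loss, not slow
  sampling, and should not donate its full length to any glucose value.
* **Coverage rule.** A trace is usable when its capped covered time
  reaches 72 h after trimming. Three full days is the smallest window we
  found to stabilize MAGE and the time-in-range fractions; the rule is a
  package default (`assess_quality()`), exposed as an argument.

Overlapping sensor blocks are an error rather than averaged: replacement
sensors are sequential in this study design, and two sensors reporting at
once indicates a data problem we refuse to paper over.

## The feature set

`extract_features()` produces, per participant:

| group | features |
|---|---|
| centrality / spread | mean, max, min, SD, CV (duration-weighted; SD in population form, since weights are durations, not counts) |
| excursions | MAGE; average rise and fall amplitude; average rise and fall rate (mmol/L/h) |
| time in range | fractions of covered time in `<3.0`, `[3.0, 7.8]`, `>7.8` mmol/L |

The normal band is closed at both edges — a reading of exactly 7.8 mmol/L
counts as normal — and the three fractions always sum to 1. The
3.0–7.8 mmol/L band (rather than the diabetes-consensus 3.9–10) is the
target range appropriate for a nondiabetic population; `time_in_ranges()`
also accepts arbitrary bands (e.g. time below 3.9) with `partial = TRUE`.

**Excursion detection.** Turning points are found on a 3-point
moving-average smoothing of the series; adjacent extrema whose raw swing
is under 0.5 mmol/L are merged into their neighbours (this suppresses
sensor jitter at 15-minute sampling without introducing a tunable
bandwidth). A monotone or constant series has no excursions; once an
interior turning point exists, the boundary segments count too.
Amplitudes are measured on the raw readings at the extremal indices.
**MAGE** is the classic definition: the mean amplitude of excursions, in
both directions, exceeding one SD of the whole post-trim trace.
Excursion *rates* are per-event amplitude/duration averaged across events
— a mean of ratios, not a ratio of means.

## ADA labeling

`classify_glycemia()` applies: diabetes if fasting ≥ 7.0 mmol/L, 2-hour
≥ 11.1 mmol/L or HbA1c ≥ 6.5 %; else prediabetes if fasting in [5.6, 7.0),
2-hour in [7.8, 11.1) or HbA1c in [5.7, 6.5); else normoglycemia. Lower
band edges are inclusive. Per-criterion flags record which channel fired.
Two consequences are load-bearing for everything downstream:

* the HbA1c ≥ 5.7 % rule has **specificity exactly 100 %** against these
  labels, on any cohort, with zero variance across splits;
* restricted to the HbA1c < 5.7 % stratum it has **sensitivity exactly
  0 %** — it cannot find what it defines away.

Participants labeled diabetes are excluded upstream of modeling, mirroring
a screening study population without known diabetes.

## Models and the 2-step strategy

Three nested predictor sets: `demo` = {age, sex, BMI, waist-to-hip ratio};
`cgm` = demo ∪ the 13 CGM features; `hba1c` = cgm ∪ {HbA1c}. Sex is a
single binary indicator; ethnicity is deliberately not a predictor.

Columns are standardized on the training rows only. LR is unpenalized
`stats::glm` (stable at p ≈ 18 with a few hundred training rows; rank
deficiency on small cohorts is tolerated). The SVM is `e1071::svm` with an
RBF kernel, cost 1, and kernel width from the median pairwise-distance
heuristic on the training rows — none of these choices are given by the
study design, so they are fixed, auditable defaults. Hard classification
sits at the natural operating point (probability 0.5 for LR, decision
value 0 for SVM); no threshold tuning is performed anywhere.

The **2-step strategy** (`score_two_step()`) hard-classifies every row
with HbA1c ≥ 5.7 % as positive and applies the model — trained on *all*
training rows, not only the low-HbA1c stratum — to the rest. Forced
positives receive a score strictly above every model score (not
probability 1.0, which a model could tie), so the combined ranking and its
ROC curve are well defined. Two structural facts follow for any dataset:
the 2-step positive set is a superset of the plain rule's, hence its
sensitivity is never lower and its specificity never higher than the
benchmark's, split by split.

## Evaluation

`run_experiment()` draws stratified 70/30 train/test splits (the 70/30
fraction is a package default, exposed in the scheme), fits on the
training rows, scores the test rows under the configured strategy, and
averages misclassification, sensitivity, specificity, ROC AUC and PRC AUC
across splits, reporting the normal-approximation 95 % CI of the mean
(mean ± 1.96 SD/√n). ROC AUC is the rank-based Mann–Whitney estimator with
tie correction; PRC AUC is step-interpolated average precision. For the
benchmark — a hard rule with a single operating point — ROC AUC is the
two-segment trapezoid (sensitivity + specificity)/2, which is also what
the rank estimator returns for a binary score with perfect specificity.

Degenerate cases are explicit: a split whose restricted test population
lacks a class is excluded from the affected metric's summary and counted;
sensitivity with no true positives is `NaN`, never a silent 0. The one
deliberate exception is the benchmark on the low-HbA1c population, which
reports sensitivity 0 (it makes no positive predictions there, yet true
positives exist) and ROC/PRC AUC 0 by reporting convention.

`threshold_sweep()` reruns the experiment over alternative segregation
thresholds, and `summarize_cohort()` produces a demographics-style
group-comparison table (Mann–Whitney U for continuous variables, Pearson
chi-square for sex/ethnicity, Fisher fallback when an expected cell count
is zero, plain 0.05 level with no multiplicity correction — matching
standard practice for a baseline table).

## The synthetic cohort generator

A single latent severity score per participant — a two-component Gaussian
mixture whose high component is the prediabetes-like group, with weight
equal to `prevalence_target` (default 0.466) — drives every measurement
channel:

* **demographics**: the high component is ~6 years older with slightly
  higher BMI and waist-to-hip ratio; sex (58.1 % female) and ethnicity
  (65.8 % Chinese, 14.0 % Malay, 15.5 % Indian, 4.7 % other) are drawn
  independently of severity;
* **OGTT channels**: fasting and 2-hour glucose are noisy linear functions
  of severity (medians ≈ 4.8 vs 5.2 and 6.1 vs 8.3 mmol/L by group);
* **CGM trace**: glucose(t) = personal night base (≈ N(4.30, 0.25) mmol/L,
  independent of severity) + a severity-linked circadian day elevation +
  three daily meal excursions (onsets jittered ±90 min, lognormal
  amplitudes scaled by a severity-linked excursion scale, ~45-min linear
  rise, 1.5-h exponential decay) + AR(1) sensor noise (stationary SD
  0.28 mmol/L, lag-15-min correlation 0.7), sampled every ~15 min with
  timing jitter, floored at 2.2 mmol/L, with 1–10 h data-loss gaps at one
  per week, and the first 24 h retained so warm-up trimming is exercised;
* **HbA1c**: a linear function of the participant's expected daytime mean
  glucose plus independent noise — the minimal structure that reproduces
  the imperfect HbA1c–glycemia concordance the whole 2-step idea exploits.

Two modeling choices deserve their own justification. First, the circadian
elevation is a raised cosine with a *flattened nocturnal window* (~1–5 am),
and the HbA1c link uses the population rather than the personal night
base. Both exist so that the nocturnal glucose floor — and hence the
minimum-glucose feature — carries no group signal: in the real cohort the
minimum is the one CGM metric that does not separate the groups, and
without these choices a subtle selection path (label ← HbA1c ← personal
night base) leaked group information into the minimum. Second, the default
channel parameters were fixed once by a coarse grid search
(`tools/calibrate_generator.R`) against five published cohort statistics —
prediabetes prevalence 46.6 %, HbA1c-rule sensitivity 60.3 %, prediabetes
fraction among HbA1c < 5.7 % of 26 %, mean time in 3.0–7.8 mmol/L of
96.3 %, mean time below 3.9 mmol/L of 2.9 % — and are shipped as frozen
constants with the search script in the repository.

Generation is deterministic: the cohort is a pure function of the
`generator_config()`, with per-participant trace substreams derived from
the single seed. Draws labeled diabetes are rejected and resampled, so the
emitted cohort contains none (an error is raised if a configuration
rejects more than half its draws).

### What the generator does not emulate

* The latent structure is one-dimensional. Real prediabetes is
  heterogeneous (isolated IFG vs isolated IGT phenotypes have distinct CGM
  signatures); here all channels are noisy views of one severity score. A
  consequence is that CGM features are *more* informative in synthetic
  data than in the real cohort — the CGM-model ROC AUC runs near 0.90
  where the study observed ≈ 0.72–0.74. Tests therefore assert orderings
  and structural facts (Demo < CGM < HbA1c; 2-step dominance; the
  minimum-glucose null), never the cohort's published AUC values, which
  are unattainable without the cohort.
* Meal timing is 3/day with jitter; no behavioral covariance (weekends,
  exercise, illness), no sensor drift or compliance gaps beyond Poisson
  data loss, and no covariance between demographics and trace dynamics
  beyond the shared severity.
* Distribution shapes beyond published medians/IQRs are conventions
  (lognormal BMI, Gaussian channels), not estimates.

Passing tests against this generator establishes that the pipeline's
plumbing, metrics and strategic claims are correct — not that the specific
published effect sizes would be recovered on new patients.

## Numerical and reproducibility choices

* Problem sizes in the shipped checks: calibration statistics at n = 5000
  participants (clinical channels) and 300–500 traces; structural
  properties at n = 406 with 200 splits; group contrasts at 200 per group;
  the demo pipeline at n = 60 with 50 splits. These sizes give sampling
  noise comfortably inside the asserted tolerances.
* All randomness flows from explicit integer seeds through a local RNG
  context that never disturbs the caller's RNG state; per-participant
  substream seeds stay below 2^31.
* Band edges, label cut-offs and the 0.5 mmol/L excursion-merge threshold
  are exact constants, not tolerances. Floating-point band assignment uses
  closed/open edge flags rather than epsilon nudges.
* Ties in ranking metrics: ROC AUC counts ties one half; PRC AUC evaluates
  precision only at the last index of each score tie group (equivalently,
  at distinct thresholds).

## Known limitations

Beyond the generator caveats above: the Libre-dialect reader targets the
common export layout (one metadata preamble line, record-type-0 historic
rows) and is not a general parser for every firmware revision; labels
require all three clinical channels and implement no repeat-test
confirmation logic; and the evaluation treats participants as exchangeable
— there is no household/site clustering, and no external-cohort
validation, which no internal resampling can substitute for.
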