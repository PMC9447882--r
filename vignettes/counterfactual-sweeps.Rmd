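---
title: "Counterfactual time-factor sweeps for OHCA prognostic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual time-factor sweeps for OHCA prognostic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Out-of-hospital cardiac arrest (OHCA) outcomes depend on several
prehospital time intervals at once — how long the crew takes to reach the
patient, how long until the first shock or the first adrenaline dose, and
how long the transport to hospital lasts. Classical single-factor analyses
answer "what if we had been one minute faster at X" one factor at a time,
but emergency-medical-service (EMS) planning needs the joint question: if
transport lengthens, does earlier drug administration still help, and by
how much? `ohcasweep` implements that joint, counterfactual analysis as a
reproducible pipeline:

1. train a class-weighted three-layer neural prognostic model on
   Utstein-style prehospital records, with the favourable neurological
   outcome (cerebral performance category 1–2 at one month, "CPC1/2") as
   the binary target;
2. re-predict held-out test records after simultaneously shifting **two**
   time factors over a grid of (minutes, minutes) deltas, each under its
   clinical eligibility rule;
3. render the percent change of the average predicted CPC1/2 versus the
   unadjusted baseline as a diverging heatmap.

Because real prefectural registries are not redistributable, the package
ships a synthetic cohort generator with a *known* logistic outcome model,
including transport-by-intervention interaction terms. Every stage of the
pipeline — encoding, stratified cross-validation, weight calibration, and
above all the two-factor grids — can therefore be verified against ground
truth, which a real registry never offers.

## The synthetic cohort

`generate_cohort()` draws one row per resuscitation attempt with 24
activity items: demographics (age, sex), circumstances (guideline era,
witness status and type, bystander CPR and its actions, bystander AED),
crew composition (emergency lifesaver, physician), first monitored rhythm,
interventions (defibrillation performed/count/time, adrenaline
given/count/time, medication route, advanced airway), the two adjustable
EMS intervals (call→contact, contact→hospital arrival), prehospital ROSC,
the arrest cause (used only by the inclusion filter) and the CPC1/2 label.

Marginals are calibrated to a published prefectural registry's overall
column: ~4% CPC1/2 prevalence, ~12% defibrillated, ~36% receiving
adrenaline, 40% witnessed, 52% bystander CPR. Time intervals are
log-normal — the standard right-skewed model for positive durations —
with `meanlog` set by the published median and `sdlog` by moment-fitting
the interquartile ratio (call→contact 8 [7, 10] min; contact→arrival 28
[22, 36] min; contact→shock median 4 min; contact→adrenaline 16 [12, 21]
min). A log-normal cannot reproduce the asymmetric published IQR of the
shock delay exactly (its implied quartiles are [2, 8]); the median is
matched and the spread approximated.

Two structural choices deserve note:

* **Eligibility coherence.** The generator never defibrillates a patient
  whose first monitored rhythm is non-shockable, and intervention times
  exist only when the intervention happened. Real registries record some
  shocks after rhythm conversion, which is why a registry can report 12%
  defibrillated with only ~9% shockable *initial* rhythms; under the
  strict coherence rule we instead allocate 13% of records to shockable
  rhythms so the 12% defibrillation rate remains attainable. This is a
  deliberate simplification: eligibility masks in the sweep module can
  then be validated exactly.
* **Pre-filter records.** The generator emits under-18 and non-cardiogenic
  records (defaults 3% and 26%, independent, so ~72% survive filtering)
  so the inclusion filter is an exercised, tested stage rather than a
  no-op.

Missingness is missing-completely-at-random per categorical field
(default 2%, configurable per field); registries publish that missing
values exist but not their mechanism, so nothing fancier is warranted.

### The ground-truth outcome model

Outcomes are Bernoulli draws from a logistic model whose linear predictor
combines age, transport minutes, intervention delays (only for treated
records), shockable rhythm, witnessed arrest and bystander CPR, plus two
interaction terms — (transport − 28)·(defib delay − 4) and
(transport − 28)·(drug delay − 16), in log-odds per minute². All main
effects are centred at the published medians so the intercept stays
interpretable.

The default magnitudes are chosen on one principle: the generative model's
intrinsic (Bayes) discriminability should match the published prognostic
model's full AUROC of about 0.94. A weaker generative signal would make
the published 80%-sensitivity operating point unreachable for *any*
learner — the synthetic benchmark would then understate what the method
achieves on real registry data, where that operating point demonstrably
exists. The resulting values (odds ratios ~0.90/min of transport delay,
~0.80/min of defibrillation delay, ~0.88/min of drug delay, OR ~25 for a
shockable rhythm) are steep but directionally consistent with the
resuscitation literature; the negative interaction coefficients encode
synergistic worsening (delays hurt more when transport is also long).

The intercept is not a free parameter in practice: `generate_cohort()`
recalibrates it by bisection on the realized covariates so that the mean
outcome probability among *includable* records equals the configured
prevalence (the tested tolerance is |empirical − target| < 0.005 at
n = 50,000).

## Preprocessing

`apply_inclusion_filters()` retains adults (age ≥ 18 — the boundary is
inclusive) with a cardiogenic arrest and reports a tally whose rounded
inclusion percentage reproduces the published 72% on the published totals
(8,274 of 11,504).

`build_schema()` maps the 22 model inputs to exactly **145 encoded
columns**:

| encoder | items | columns |
|---|---|---|
| standardized continuous | age, defibrillation count, adrenaline count | 3 |
| raw adjustable minutes | call→contact, contact→arrival | 2 |
| one-hot + missing level | 13 categorical items | 50 |
| defibrillation: non-performance flag + one-minute time bins 0–30, 31+ | | 33 |
| adrenaline: non-performance flag + one-minute time bins 0–54, 55+ | | 57 |

Design decisions, and why:

* **Training-fold standardization only.** Means and population standard
  deviations are computed from the records handed to `fit_encode()` and
  stored; `encode_records()` never re-fits. Each cross-validation fold
  fits its own encoder on its own training records, so no information
  leaks from validation or test rows into the encoding (a property the
  suite asserts directly).
* **Adjustable transport intervals stay in raw minutes.** Counterfactual
  deltas are specified in natural units; keeping these two channels
  unstandardized means a +10-minute shift is exactly +10 in one encoded
  column and nothing else.
* **Intervention times are one-hot binned by minute**, alongside an
  explicit non-performance flag (all bins zero, flag one, when the
  intervention did not happen). This is what makes a 24-item record
  expand to 145 factors; a `intervention_time` encoder kind (flag + raw
  minute channel, two columns) is available for configurations that
  prefer a compact continuous channel. Adjustments always operate on the
  raw record and re-encode through the stored transform, so sweep
  semantics are identical under either encoding.
* Unseen categorical levels at transform time map to the missing level
  with a warning; zero-variance continuous columns fall back to scale 1.

## Stratified split and cross-validation

`stratified_split()` divides records into five groups stratified by
CPC1/2: positives and negatives are each split as evenly as possible, and
the per-class remainders go to the *same* seeded tail groups. With 8,274
records and 286 positives this reproduces group sizes
{1654, 1654, 1655, 1655, 1656} with positives {57, 57, 57, 57, 58}; class
counts differ by at most one per group (totals may differ by two — the
published table has the same property). The test group is the first group
in the seeded ordering, which by construction receives no remainder
records and is therefore the smallest. `cv_folds()` yields the four
train/validation pairs over the non-test groups; the test group appears
in none of them.

## The prognostic network

Three hidden blocks of affine → batch normalization → sigmoid activation
→ dropout, then a final affine + sigmoid output. Defaults: widths
(180, 80, 40) — chosen so one forward pass of a 145-column record costs
roughly 44,000 multiply-accumulates — dropout 0.2, batch size 100, 50
epochs, Adam at learning rate 0.001, no early stopping (the final epoch is
the model). The hidden bias is omitted under batch normalization because
the batch mean absorbs it. Batch normalization uses population (biased)
batch variance with ε = 1e-5 and running statistics with momentum 0.1;
inference disables dropout and uses running statistics, so prediction is
deterministic and batch-invariant. A rectifier activation is available as
a config switch; sigmoid is the default throughout.

Training runs in a compiled RcppArmadillo kernel; an R implementation of
the same forward/backward mathematics is kept as a reference and the two
are cross-checked to machine precision in the test suite. Analytic
gradients — including through batch normalization and fixed dropout
masks — are verified against central finite differences (relative error
< 1e-4 on a tiny network). All randomness (Glorot initialization in R,
epoch shuffling and dropout masks drawn from R's RNG inside the kernel)
derives from the configured seed, so training is exactly reproducible.

### Class-weight calibration

At ~4% prevalence an unweighted model simply predicts "no". The loss is
therefore the class-weighted binary cross-entropy, mean of
`-(w_pos·y·log p + w_neg·(1−y)·log(1−p))` with `w_neg = 1`.
`calibrate_class_weights()` searches for the smallest `w_pos` whose
validation minority-class sensitivity reaches the 80% target (tolerance
0.02): a geometric walk 1, 2, 4, …, 64 stopped at the first qualifying
weight, then geometric bisection between the last failing and first
qualifying weights (three refinements by default). Choosing the smallest
qualifying weight keeps the majority-class sensitivity — which controls
how many false CPC1/2 predictions dilute the counterfactual summaries —
maximal among qualifying weights. If nothing on the grid qualifies, the
best-achieving weight is returned with an explicit failure flag. Each
cross-validation fold is calibrated independently; the classification
threshold stays at 0.5 throughout (weighting, not thresholding, is the
operating-point control). Evaluation reports per-class sensitivities,
their unweighted mean, and the rank-based AUROC with a DeLong 95% CI
(deterministic, unlike a bootstrap; provided by pROC).

## Counterfactual sweeps

An `adjustment_spec()` names one factor, its eligibility rule and a clamp
floor (0 min): age and the two transport intervals apply to everyone; the
defibrillation delay only to defibrillated patients with a shockable
initial rhythm; the drug delay only to adrenaline recipients whose arrest
was not witnessed by EMS personnel (firefighter, paramedic, emergency
lifesaver — for those, "earlier drug administration" is not a meaningful
counterfactual). Adjusted values are floored at zero rather than dropped;
`adjust_records()` never mutates its input and never touches ineligible
rows, a property asserted bit-for-bit.

`two_factor_grid()` applies every delta pair simultaneously, re-encodes
through each model's stored transform, averages the four models'
predicted probabilities over the **entire** test set (ineligible records
dilute the change, matching a baseline defined on the full unadjusted
test data), and reports each cell as
`100·(adjusted − baseline)/baseline`. The (0, 0) cell is exactly zero by
construction. The default summary is the mean predicted probability; a
thresholded predicted-positive count mode is also implemented because
"average predicted CPC1/2" admits both readings, and every output records
which mode produced it. An absolute (percentage-point) mode is likewise a
flag. Default axes are ±10 min for transport and ±5 min for intervention
delays, as config values. Each grid also records per-factor eligible
counts and, when training records are supplied, the fraction of adjusted
test values inside the central 98% range of the training values — a
trained-region diagnostic, since cells built from sparsely trained
regions extrapolate and mislead.

`render_heatmap()` draws the grid with a diverging scale clipped
symmetrically at ±6% (out-of-range cells render at the extreme) and a
black box outlining the zero-adjustment cell.

### Reading interactions out of a grid

Percent changes compound multiplicatively: even a purely additive
log-odds model yields `cell(i,j) ≈ (1+cell(i,0))(1+cell(0,j)) − 1`, so a
raw additivity residual is positive whenever both single-factor effects
share a sign. Interaction is therefore assessed on `log1p(cell/100)`:
there, a no-interaction model's residual is first-order zero (small
heterogeneity and eligibility-dilution terms remain), and a synergistic
(negative) generative interaction produces a clearly negative residual.
The parameter-recovery test averages this residual over the corner region
where both factors are delayed by ≥ 5 min, where the γ·a·b term is
largest.

## Problem sizes used by the tests

The suite verifies the pipeline at sizes a reviewer can run on a laptop
core, chosen as the package's own desk-scale experiment design:

* Calibration operating point: five replicates of an 8,000-record cohort
  at the registry's 4% prevalence, one CV fold each (the acceptance
  script reports the mean validation minority sensitivity the same way).
* Parameter recovery: five replicates of a 6,000-record cohort at **10%**
  prevalence with the default effect model and a fixed class weight of 9.
  The raised prevalence is a power choice made at design time: at 4%, a
  1,000-record test group holds ~40 positive-class records and the
  corner-region residual is dominated by Monte-Carlo noise; at 10% the
  interaction sign is recoverable while everything else (structure,
  eligibility, grids) is unchanged. The test requires the recovered
  transport axis to be monotone and the corner residual negative in at
  least four of the five replicates.
* Oracle equivalence: a deterministic logistic stub predictor on 100
  records, 5×5 grid, compared cell-by-cell against an independent
  brute-force recomputation at 1e-10 relative tolerance.

## What passing tests do and do not show

The generator emulates marginal distributions, eligibility rules,
imbalance, missingness and a known interaction — not the full joint
structure of a real registry: no temporal or geographic drift, no
rhythm-conversion dynamics, no dependence between time intervals beyond
the outcome model, no informative missingness, and covariates drawn
largely independently given the modelled effects. Passing the recovery
tests shows the *pipeline* faithfully propagates and exposes interactions
a data-generating process contains; it does not certify that any real
registry contains them, nor that a model trained on one region transfers
to another. The published caveat applies to synthetic and real data
alike: cells far from the trained region (e.g. defibrillation delays
shifted beyond the few minutes actually observed) reflect extrapolation,
which is why grids carry the trained-coverage diagnostic.

## Numerical and reproducibility notes

* Probabilities are clipped at 1e-12 for loss evaluation; gradients use
  the exact sigmoid-cross-entropy form `s·(p − y)/m`, which needs no
  clipping.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8 with bias correction.
* A trailing mini-batch of fewer than 2 rows is merged into the previous
  batch (batch statistics of a single row are undefined).
* Every stage derives its own seed from the master seed; identical config
  and seed reproduce identical CSV artifacts byte for byte (hashed in the
  run manifest). Package internals save and restore the caller's RNG
  state.
* Ties in AUROC count one half, per the Mann–Whitney convention.
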