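---
title: "Digital frailty biomarkers from the five-times sit-to-stand test: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital frailty biomarkers from the five-times sit-to-stand test: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsfrailty)
```

## The problem

The five-times sit-to-stand test (5xSTS) — rise from and return to a chair
five times, as fast as possible, arms folded — is a standard clinical probe
of lower-limb function in older adults. Worn inertial sensors on the trunk,
thighs and shanks turn the test into a rich kinematic recording: sagittal
pitch angles of each segment plus vertical trunk displacement, sampled at
100 Hz. From such a recording this package computes candidate *digital
biomarkers* of physical frailty and ties them to three phenotypes of the
Fried frailty screen: **slowness** (velocity-type features), **weakness**
(angle- and power-type features) and **exhaustion** (cycle-to-cycle
variability features).

The analysis pipeline is:

1. **Feature extraction** — segment the recording into its five stand–sit
   cycles and compute 17 features: the 5xSTS duration plus the mean and
   coefficient of variation (CV = SD/mean, sample SD with the n−1
   denominator over the 5 cycles) of eight per-cycle *range* signals
   (hip/knee angle, hip/knee angular velocity, hip/knee angular power,
   vertical velocity, vertical power); range = max − min within a cycle.
2. **Screening** — per feature, a two-group comparison of robust (status 0)
   vs pre-frail/frail (status 1) subjects, routed by Shapiro–Wilk normality
   to either a classical one-way ANOVA or a two-sided Mann–Whitney U test;
   features with p < α survive.
3. **Ranking** — bootstrapped recursive feature elimination (RFE):
   B resampled training sets with out-of-bag (OOB) validation sets; at each
   elimination loop one logistic model per remaining feature is fitted
   *excluding* that feature, its OOB AUC is averaged over the B pairs, and
   one feature is removed; rank 1 is the last survivor.
4. **Selection** — the smallest top-k subset that covers all three
   phenotypes and exceeds a mean validation AUC threshold (default 0.80).
5. **Evaluation** — bootstrap-validated AUC, sensitivity, specificity and
   accuracy (= (TP+TN)/(TP+TN+FP+FN)) of the selected subset, each with a
   mean and 95% CI over the B validation sets, reported in percent.

A fixed-coefficient logistic scorer is also provided
(`published_frailty_model()`): logit p = 2.722 − 0.022·ph₁ + 0.243·ph₂ +
0.055·ph₃, where ph₁ is the mean hip angular velocity range, ph₂ the mean
vertical power range and ph₃ the CV of vertical power range. Because the
coefficients are fixed constants, the scorer documents its unit assumptions
(deg/s, W, percent) rather than rescaling inputs.

## Kinematic and kinetic definitions

Joint angles use a simple sagittal convention on segment pitch measured
from vertical: hip = trunk − thigh, knee = thigh − shank. Angular power is
I·α·ω (= τ·ω), with segment moments of inertia from the de Leva-adjusted
Zatsiorsky–Seluyanov anthropometric table embedded as a package constant
(trunk inertia for the hip, thigh inertia for the knee; I = m·(k·L)² with
segment mass and length fractions of body mass and height). Vertical power
is m·v·a from body mass and the first and second derivatives of vertical
displacement. A dimensionless vertical-power scaling is available in two
forms: the default divides by m·g²·h, and `form = "conventional"` divides
by m·g·√(g·h); the 17-feature set itself uses raw vertical power in W.

Derivatives are central differences (one-sided at the endpoints) after
zero-phase low-pass filtering at 6 Hz — standard pre-conditioning for
human-movement kinematics at 100 Hz, where sit-to-stand energy lies below
~3 Hz. The filter is a linear-phase FIR (windowed-sinc, 59 taps at 100 Hz,
delay compensated, kernel normalized to unit DC gain, edge-reflection
padding), chosen over forward–backward IIR filtering for one decisive
property: a finite symmetric convolution is exactly translation invariant,
so identical movement cycles in identical local context filter to
bit-identical outputs (and jitter-free synthetic subjects therefore have
exactly zero CV features), while IIR transients decay across the recording
and leave cycle-to-cycle differences at the 10⁻⁵ level. The kernel's
passband is flat to ~0.3% through 3 Hz, and its half-width (0.29 s) is
shorter than the shortest seated pause, so no cycle's filtered values
depend on a neighbouring cycle.

## Cycle segmentation

Cycles are found on the thigh pitch channel — the segment with the largest,
most stereotyped sit-to-stand excursion. The filtered signal is normalized
to its global amplitude and passed through a hysteresis state machine
around the 50% amplitude level (switching bands at 40% and 60%): dropping
below the 40% band opens a standing episode, returning above the 60% band
closes it. Each episode is then extended outward *on the raw signal* to the
last/first samples still at the seated baseline, within a tolerance of
max(5·noise SD, 10⁻⁶ of the amplitude). The baseline and the noise SD are
estimated on the seated plateau *core*: samples in the top 5% of the
normalized amplitude whose whole filter window also lies there, so that
transition smear cannot contaminate the raw-minus-filtered residual. On
clean signals an interval therefore spans the full seated-to-seated
movement and matches the generating cycle duration to within one sample. A trial whose episode count is not exactly five is flagged invalid
with the count attached (`sts_invalid_trial`); cohort extraction excludes
and reports such trials rather than dropping them silently. The sensor-based
5xSTS duration is (offset − onset)/fs, from the first cycle's onset to the
last cycle's return to sit.

Degenerate inputs: a thigh amplitude below 0.1 rad is treated as
movement-free (0 cycles); a per-cycle range summary with |mean| < 10⁻⁹
reports an undefined (NA) CV rather than an infinite one; and a per-cycle
SD below 10⁻¹⁰ + 10⁻⁹·|mean| reports a CV of exactly 0, which absorbs
floating-point-level differences between bit-identical cycles that passed
through the global filter.

## The synthetic cohort

Real 5xSTS sensor cohorts are not publicly deposited, so the package ships
a seeded generator that serves as the test bed for every downstream stage.
Defaults describe a cohort of 42 robust and 60 pre-frail/frail older
adults at 100 Hz.

Each subject draws movement parameters from Gaussian between-subject
distributions (robust baselines: cycle duration 1.2 ± 0.15 s, pause
0.3 ± 0.05 s, thigh excursion 1.30 ± 0.10 rad, trunk lean 0.35 ± 0.05 rad,
vertical rise 0.25 ± 0.03 m, cycle-to-cycle CV 0.05 ± 0.015; anthropometrics
per group, with the pre-frail/frail group heavier on average). Frail
subjects' means are shifted by a standardized effect profile — by default
+1.0 SD on timing, −0.3 SD on amplitude, −0.8 SD on vertical rise and
+1.5 SD on variability. These act on *generator parameters*, not on
features: slower angular velocities, lower powers and higher CVs emerge
through the extraction stage, which is exactly what makes the
direction-consistency tests meaningful. The magnitudes were chosen once as
plausibly strong clinical contrasts that make roughly half the feature set
separate the groups at n ≈ 100; they are fixtures of the test bed, not
estimates of any real cohort.

The waveform model uses raised-cosine thigh transitions between the seated
(1.40 rad) and standing (0.10 rad) pitch, a single forward trunk-lean pulse
per cycle, a small (0.08 rad) shank modulation and a smoothstep vertical
rise, with phases rise/dwell/return = 40/20/40% of the cycle. These shapes
are smooth, twice differentiable and have analytic derivatives, so
`recording_truth()` can supply closed-form per-cycle durations and ranges
as an independent oracle for recovery tests. Per-cycle durations and
amplitudes are jittered with relative SD `cycle_cv`; cycle start times are
snapped to the sample grid so a jitter-free subject has bit-identical
cycles (and hence exactly zero CV features). White noise of SD `noise_sd`
(default 0.01 rad) is added to the angle channels only.

Randomness is split per subject by counter from the cohort seed, so
enlarging a cohort never perturbs earlier subjects, and everything is a
pure function of the spec.

A second, direct generator (`simulate_feature_table()`) emits the 17
features straight from independent Gaussian distributions with planted
standardized shifts. It deliberately has *no* correlation structure between
features, which real biomechanical features certainly have; it exists to
give the screening and selection stages exactly known ground truth (type-I
rates, planted-effect recovery, analytic AUC limits). Consequently, passing
tests demonstrate correctness of the procedures under known truth — not
that the procedures would select the same features in a real cohort, where
correlated features make leave-one-out importance intrinsically harder.

## Screening choices

Normality is assessed per group; the ANOVA route is taken only when *both*
groups pass Shapiro–Wilk at α — the conservative standard when a published
routing rule does not state its grouping. The screening α is 0.05, with no
multiplicity correction by default (a Benjamini–Hochberg option exists but
is off, matching common practice for this kind of descriptive screen). The
Mann–Whitney branch is exact when the smaller group has ≤ 8 subjects and
there are no ties, otherwise the normal approximation with tie correction.
The two-group ANOVA is the classical equal-variance one (its F equals the
squared pooled t, which the tests exploit as an oracle identity).

## Selection procedure choices

Several details of a bootstrapped RFE are genuinely open; the package fixes
them as follows.

- **Validation sets are out-of-bag.** Training sets are drawn with
  replacement (stratified by class by default, preserving class counts);
  the validation set is the complement of the training support. Draws with
  a single-class training or OOB set are redrawn — at n ≈ 100 this is
  vanishingly rare but prevents degenerate fits. The expected OOB fraction
  is (1 − 1/n)ⁿ ≈ 36.6% at n = 102.
- **Elimination direction.** Each candidate's score is the AUC of the model
  *excluding* it, so the feature whose exclusion model scores **highest**
  is the one the model needs least, and that is what the default removes
  (`direction = "least_informative"`). The literal opposite reading
  ("remove the lowest-AUC feature") is available as
  `direction = "literal"` for comparison, but it would discard the most
  informative feature first and invert the ranking semantics.
- **Fit counting.** One leave-one-out model per remaining feature per
  bootstrap pair, while ≥ 2 features remain: B·Σ_{k=2..K} k fits in total —
  70,000 for K = 8, B = 2000. The executed count is instrumented
  (`fit_count()`) and checked against the analytic formula.
- **Per-k subset AUCs** (used by the selection rule and the
  performance-vs-size curve) reuse the *same* B bootstrap pairs as the
  elimination loops, for comparability across k. A consequence worth
  knowing: on pure-noise features the top-k subsets are chosen *on the same
  splits they are scored on*, so their null AUCs scatter around 0.5 with a
  winner's-curse lift of a few points — the null-calibration tests assert
  exactly that behaviour.
- **Ties** on mean AUC eliminate the candidate earliest in canonical
  feature order — deterministic and documented; with continuous features
  exact ties essentially never occur.
- **Logistic fits** are unpenalized maximum likelihood with an iteration
  cap; perfect separation or non-convergence is flagged, and the capped
  estimate's scores remain usable for AUC (rank-based, so monotone-invariant).
  Aliased (constant) columns get coefficient 0 rather than NA so scoring
  never fails.
- **B = 2000** bootstrap pairs is the reference setting at n ≈ 100; tests
  and examples scale B down (1–500) since Monte-Carlo error in a mean AUC
  shrinks as 1/√B and ranking stability, not CI width, is what the smaller
  runs exercise.

## Evaluation choices

The operating threshold for sensitivity/specificity/accuracy is a 0.5
posterior probability; no published operating point exists for this family
of models, and 0.5 is the neutral default. AUC is computed by the rank
(Mann–Whitney) formulation with half-weight ties. CIs are percentile
(2.5/97.5) across the B per-pair metric values by default; a
mean ± 1.96·SE/√B variant (`ci = "sem"`) is provided because per-iteration
SEM intervals are what very narrow published CIs of bootstrap means imply,
and the report records which method produced it. Metrics are reported in
percent; internally they are proportions.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
cohorts of 102 subjects (42/60). The heavier checks use: one full
elimination run at B = 2000 (70,000 fits); 20 replicate cohorts at B = 200
for planted-subset recovery (3 planted features at d = 1.5 among 8);
10–20 replicate cohorts at B = 200 for the two-Gaussian AUC limit
(population AUC Φ(d/√2) = 0.7602 at d = 1); and 400–1000 zero-effect
tables for null calibration of the 5% screening rate. These sizes keep
Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

- The orientation pipeline is deliberately thin: the package consumes
  segment pitch and vertical displacement series and does not implement
  quaternion/IMU sensor fusion, gravity estimation or frontal/transverse
  angles.
- The waveform generator is a stylized kinematic model — no double support
  asymmetries, tremor, partial rises or compensatory strategies — so
  segmentation robustness is demonstrated only against additive noise and
  timing/amplitude jitter.
- The direct feature-table generator's independence assumption understates
  the difficulty of feature ranking on real, correlated biomechanics.
- The fixed-coefficient scorer's input units are assumptions recorded in
  its documentation; applying it to features in other units requires
  caller-side conversion.
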