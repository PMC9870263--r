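---
title: "A single-axis rotation model for hip and knee flexion from three IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-axis rotation model for hip and knee flexion from three IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The model

Three orientation sensors are worn on the sacrum, right thigh and right
shank, mounted so that each case's longitudinal ("roll") axis is parallel
to the segment's long axis and to the other sensors'. During sagittal
gait the segments rotate mainly about this shared axis, so a single angle
per sensor carries the kinematic signal:

- knee flexion = thigh roll − shank roll,
- hip flexion = sacrum roll − thigh roll,

with flexion positive. The model's two structural assumptions are (1)
parallel roll axes (violated alignment appears as crosstalk from other
rotation planes) and (2) that a roll *difference* is meaningful even when
each individual roll contains a common-mode component — pelvis roll, or a
whole-body rotation — because the subtraction cancels it exactly
(`knee_flexion()`/`hip_flexion()` are element-wise differences and the
test suite asserts common-mode invariance).

### Roll extraction and heading immunity

Sensors deliver unit quaternions. Roll is the innermost angle of an
intrinsic Tait–Bryan decomposition whose *first* axis is vertical
(default `ZYX`: yaw–pitch–roll, roll about x). Any heading rotation
premultiplies the rotation matrix and leaves its bottom row unchanged,
and `roll_from_quaternion()` computes roll from that row only — so the
magnetometer-derived yaw, the component most exposed to magnetic
disturbance, cannot affect the result by construction. The convention is
configurable (`ZXY` for hardware whose long axis is y) because vendors
differ and the mounting decides which body axis is longitudinal.

Numerical edge cases: quaternions must be unit-norm within `1e-6` (they
are renormalised; beyond tolerance is an error naming the norm); at
gimbal lock (pitch within `1e-6`° of ±90°, far outside the sagittal gait
range) the roll/yaw split is ill-conditioned, so the function warns and
returns the two-argument arctangent value rather than failing. Extracted
roll is wrapped to (−180°, 180°]; `unwrap_degrees()` restores continuity
by adding whole turns whenever a successive difference reaches 180°, and
is idempotent.

### Zeroing

Each joint's offset is the arithmetic mean of its angle over a 10-s
standing trial in the anatomical position; `apply_zeroing()` subtracts
it once (double zeroing is an invalid-state error). Sensor-derived
angles are always zeroed before validation. Reference angles are carried
in both raw and zeroed variants, because the comparison between them
isolates what a static calibration can and cannot fix: a constant offset
moves the Bland–Altman bias only, never the spread. By default the
offset averages the full trial; `calibration_window = "central"` keeps a
centred fraction (default 0.8) to exclude postural sway while settling —
a judgment call the protocol leaves open, defaulting to the simpler
full-trial mean.

## Time alignment

The sensor and camera systems start independently, so their streams are
offset by an unknown clock lag. `align_by_xcorr()` maximizes the Pearson
correlation of the mean-removed overlapping segments over integer lags in
±`max_lag_s` (default 5 s). Integer-sample search is sufficient because
both systems sample at the same 60 Hz; subsample interpolation would add
a resampling model the data do not require. Mean removal matters: a
constant inter-system offset must not bias the lag. Ties (possible on
near-periodic gait) resolve deterministically to the smallest |lag|,
then the negative one. Constant input has no defined lag and errors. One
lag per trial is estimated on the knee signal — the larger excursion
gives the sharper correlation peak — and applied to both joints;
`align_mode = "per_joint"` estimates separately when the streams are not
jointly recorded.

## Agreement statistics

For aligned pairs `d = sensor − reference`:
bias `M_dif = mean(d)`; `Sd = sd(d)` using the sample (n−1) estimator
(standard Bland–Altman practice); repeatability coefficient
`RPC = 1.96·Sd`; limits of agreement `M_dif ± RPC`. The regression is
OLS of reference on sensor (`reference = m·sensor + b`): with the sensor
as predictor, a knee slope below 1 reads as the sensor overestimating
knee flexion excursion; the orientation is switchable. MAE and RMSE are
plain means over the pair. Per-participant metrics are computed per
joint, timepoint and reference variant, then averaged across participants
for the summary table; pooling all participants' samples into one
Bland–Altman/regression pass is a separate surface (`report$pooled`),
not a replacement — the two answer different questions (typical
participant vs population scatter). T1-vs-T2 differences use two-tailed
paired t-tests per metric at α = 0.05 with no multiple-testing
correction across the nine metrics, and the participant — not the pooled
sample — as the unit of analysis. Zero-variance paired differences make
t undefined; the implementation reports p = 0 when the mean difference is
non-zero and p = 1 otherwise, with a warning, so degenerate inputs stay
deterministic.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` reproduces the study conditions: 20 participants,
60 Hz, a 10-s standing calibration, and two walking trials (T1/T2) of
60 s each from which the second 20-s period (1200 samples) is analyzed —
hence 24,000 pooled samples per joint and timepoint.

**Truth.** Flexion waveforms are harmonic series over the gait cycle.
Defaults: cycle 1.1 s; hip = 10° + 20°·cos(phase); knee = 25° +
22°·cos(phase + 1.88) + 13°·cos(2·phase + 3.77), which puts the knee
peak (~60°) about 70% through the cycle and keeps both joints inside
physiological envelopes (knee [−5°, 90°], hip [−30°, 60°]; construction
errors outside them). Cycle durations are jittered (normal, cv 0.03,
truncated at 3 sd) for stride-time variability. Per-participant
parameters are drawn uniformly from `cohort_ranges()`: cycle 1.0–1.2 s,
amplitude scale 0.9–1.1, baselines ±2°, standing pose 0–4° (hip) and
1–6° (knee) residual flexion.

**Segment rolls.** Solved exactly from the model's inverse
(sacrum = pelvis roll, thigh = sacrum − hip, shank = thigh − knee), with
a small periodic pelvis roll (1–3°) as common-mode content; with zero
corruption the full chain — rolls → quaternions → extraction → joint
model → zeroing — returns truth to better than 1e-9°, which anchors
every later recovery test.

**Corruption.** Per sensor: a constant mounting offset (±3°), white
noise (0.2–0.5°), linear drift (0–0.5°/min), and a soft-tissue artifact
— the adjacent joint's mean-removed excursion, low-pass filtered at 4 Hz
(2nd-order Butterworth, zero-phase) and scaled by a gain of 0.02–0.08 —
applied to the muscle-mounted thigh and shank only, since the sacrum
sensor sits over bone. At T2 an extra offset emulates attachment-tape
degradation after ~40 minutes of walking: concentrated on the shank
(−3 to −1°) with a smaller thigh component (+0.2 to +1.2°), signed so the
knee reads consistently higher at T2 — giving the qualitative pattern of
a knee bias/MAE increase and an intercept drop while the hip stays
comparatively stable. Each sensor also gets a random constant heading, so
the pipeline continuously exercises heading immunity. The camera-like
reference receives independent 0.3° white noise, a constant offset of
±1° (so the raw/zeroed reference distinction has content), and an
integer clock lag drawn from ±120 samples (±2 s).

A master seed expands into per-participant, per-trial sub-seeds through a
fixed linear scheme, so cohorts are bitwise reproducible and any single
trial can be regenerated. `noise_free_ranges()` collapses every noise,
offset, jitter and lag range to zero for exact round-trip checks.

**Not emulated:** marker-model kinematics (the reference is truth plus
noise, not a simulated marker pipeline), magnetic disturbance (the model
discards heading by construction), non-sagittal crosstalk from imperfect
sensor alignment, treadmill-speed dynamics, and pathological gait. A
passing suite therefore shows the *pipeline* is correct and the
statistics behave as designed under realistic noise magnitudes — it does
not certify accuracy of the physical sensor system on any real
population.

## Problem sizes and determinism

The shipped tests and examples run cohorts of 1–20 participants with
60-s trials at 60 Hz; Monte-Carlo noise checks use up to 12,000 samples.
These sizes give sub-minute runs while leaving every statistical check
well-powered (e.g. a white-noise sd estimate over 12,000 samples has a
~0.6% standard error against a ±5% assertion band). Report JSON is
written with 6-decimal formatting so identical inputs yield byte-identical
files.

## Known limitations

- The operand order hip = sacrum − thigh is one of two sign conventions
  in circulation; `run_config(hip_sign_flip=, knee_sign_flip=)` flips a
  joint rather than silently reconciling descriptions that disagree.
- Integer-lag alignment leaves up to half a sample (~8 ms at 60 Hz) of
  residual offset; at gait frequencies this is negligible against the
  noise floor but would matter for impact transients.
- The agreement battery assumes both streams share one sampling rate;
  resampling between rates is out of scope.
- RPC assumes approximately normal differences; heavy-tailed soft-tissue
  artifact makes the 95% coverage of the limits of agreement nominal
  rather than exact.
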