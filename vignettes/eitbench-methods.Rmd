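---
title: "Methods: simulating and evaluating a 16-electrode chest EIT device"
author: "eitbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a 16-electrode chest EIT device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitbench)
```

## Scope and model overview

`eitbench` reproduces, on fully synthetic data, the evaluation methodology
used for 16-electrode chest electrical impedance tomography (EIT) devices:
a breathing thorax phantom drives a finite-element forward model, frames
are reconstructed with a GREIT-style linear map, the reconstructed image
sequences are reduced to the standard clinical ventilation-distribution
indices, and repeated recordings from two emulated devices are compared
with equivalence and agreement statistics. A separate bench branch
emulates the resistor-network quality-control recording from which
per-channel SNR and drift are computed.

Everything is 2D, time-difference, and linear-by-design where the field's
consensus method is linear. Absolute imaging, 3D modelling, cardiac
signals and real device file formats are out of scope.

## Forward model

The conductivity equation is discretized with linear (P1) triangles on a
structured mesh of a disk or ellipse normalized to unit bounding radius
(`build_thorax_mesh()`). Conductivity is piecewise constant per element.
The 16 electrodes enter through the complete-electrode model (CEM):
contact impedance terms on the electrode boundary edges, one floating
potential unknown per electrode, and current conservation per drive
pattern. The constant-potential null space is removed by grounding the
centre node; all measurements are electrode-pair differences, so the
choice of ground does not affect them.

Stimulation follows the adjacent (neighbouring) convention of this device
class: 16 adjacent drive pairs at 5 mA, and for each drive the 13
adjacent measurement pairs that share no electrode with the drive,
giving 208 measurements per frame. The carrier frequency (100 kHz) is
metadata only; the forward model is quasi-static.

Numerical choices worth stating:

* **Contact impedance** defaults to 1e-3 ohm-metre (2D CEM units), small
  against the tissue impedance scale of roughly 2 ohm-metre. The exact
  Ohmic scaling identity ("double the conductivity, halve the voltages")
  holds for the CEM only when conductivity and contact *admittance* are
  scaled jointly; with the small default contact impedance the
  conductivity-only version holds to well under 1%, which is how the
  package's tests state it. The electrode geometry (each electrode spans
  half of its 22.5-degree sector) is a documented default, not a measured
  device property.
* **Mirror symmetry.** Node coordinates are made bit-exactly symmetric
  about the ventral-dorsal axis and quad diagonals are chosen by the sign
  of the quad-centre x (axis-straddling quads get a 4-way split), so a
  symmetric phantom produces right/left-symmetric images to solver
  precision. Right/left comparisons in the test-suite rely on this.
* **Jacobian** by the adjoint method: the sensitivity of measurement
  (drive d, pattern m) to an element's conductivity is
  `-(area/I) grad(u_d).grad(u_m)`, with the measurement field reusing the
  drive solutions because adjacent measurement patterns coincide with the
  drive patterns. Tests pin this against one-sided finite differences and
  the conductivity-homogeneity identity `J sigma = -v`.
* **Point-electrode mode** is a test-only fallback used to compare the
  solver with the closed-form boundary potential of a homogeneous disk,
  `u = (I/(pi sigma)) ln(|z - z_sink|/|z - z_source|)`. At even
  refinement a mesh node lies exactly on each electrode centre and the
  agreement is a few tenths of a percent.

The mesh grows with `refinement`: 32r boundary nodes and 6r rings, i.e.
372 elements at r = 1 and 1472 at r = 2. Index work and statistics run at
r = 1; the full-pipeline linearity check runs at r = 2. These sizes are
the package's chosen working points: they are fine enough that the
reported quantities are mesh-stable at the tolerances tested.

## Breathing phantom and synthetic data

The phantom (`phantom_config()`) is a homogeneous background
(0.48 S/m) with two elliptical lungs (semi-axes 0.32 x 0.45, centres at
x = -0.45 and +0.45, slightly dorsal at y = -0.05; the subject's right is
at negative x). Lung conductivity is coupled linearly to regional lung
volume above functional residual capacity:

    sigma(t) = sigma_exp - k * w_region * V_region(t)

with `sigma_exp = 0.24` S/m at end-expiration, swing `k = 0.02` S/m per
litre, and regional ventilation weights `w_right + w_left = 1`. Air
lowers conductivity, so inspiration decreases sigma. The linear coupling
makes the ground truth unambiguous: the configured right weight *is* the
true right-lung ventilation fraction. The swing default keeps the
relative conductivity contrast under ~20% across a 4 L vital capacity,
inside the small-contrast regime in which a linear time-difference
reconstruction is the appropriate tool; larger swings are accepted but
push the forward map visibly outside the linear regime. Optional
per-lung first-order lags on `V(t)` inject known regional ventilation
delay; an optional dorsal weighting skews the swing within each lung.

The breathing protocol is the maneuver the evaluation methodology
prescribes: relaxed tidal breathing followed by one slow vital capacity
(SVC) excursion. Defaults: 3 tidal breaths of 0.5 L with a 4 s period,
then a 4 L SVC with 4 s inspiration and 4 s expiration, sampled at
50 Hz. Tidal volumes and vital capacity are configuration, not measured
values. The matched spirometry trace is sampled at 25 Hz — deliberately
different from the frame rate so that every volume-impedance comparison
must exercise the linear-interpolation step.

Measurement noise is multiplicative Gaussian per measurement (relative
SD 5e-4 by default, about 66 dB, comfortably inside the 60 dB device
class bound), plus an optional linear gain drift. The four-recording
device comparison (`emulate_two_devices()`) shares a single noiseless
forward simulation and draws four independent noise realizations in the
measurement order A, B, A, B.

What the generator does *not* emulate: cardiac-related impedance
oscillations, posture changes, electrode detachment, belt repositioning
error between repetitions, and anatomical thorax contours. Passing tests
therefore demonstrate the correctness and calibration of the analysis
chain, not robustness to those real-data effects; in particular the
repeatability variability reported by `run_study()` reflects measurement
noise only and is much smaller than belt-repositioning variability in
human measurements.

## GREIT reconstruction

`greit()` trains the linear map R from normalized difference data
`dv = (v - v_ref)/v_ref` to a 32 x 32 masked pixel image. Training
targets are small conductivity-decrease blobs (radius 0.08 of the domain
radius) centred on the in-domain points of the pixel-centre grid
(~800 targets; a uniform deterministic grid rather than random
placement, for reproducibility). Target data are simulated through the
Jacobian; desired images are uniform disks of radius 0.1 with unit pixel
sum. R solves the regularized least-squares problem

    R = Xd Y' (Y Y' + lambda^2 Sigma_n)^(-1)

with diagonal noise covariance at the configured device noise level.
Reciprocity makes the 208 measurements pairwise redundant, so `Y Y'` is
rank-deficient and some regularization is always required; lambda is
calibrated by a deterministic monotone 1-D root search so that the noise
figure — measurement SNR over image SNR for the central training
target — hits its target (default 0.5) within the root-finder tolerance.
The achievable noise-figure range is bounded below by the
strong-regularization limit (about 0.4 for the default geometry);
requests below it fail with bracketing diagnostics rather than silently
clamping. All GREIT hyperparameters are arguments, none are hard-coded.

The reference frame for difference imaging defaults to the first
detected end-expiration (`reference = "auto"`: a provisional
reconstruction against frame 1 is segmented, then the data are
re-referenced), falling back to frame 1.

Training on the same mesh that generated the data is an inverse crime in
the strict sense; it is also exactly what a device-evaluation pipeline
does when it reconstructs both devices' data with one offline algorithm,
and the indices under study are relative, not absolute. The
position-error and parameter-recovery tests bound the consequences.

## Ventilation indices

All indices operate on the reconstructed image sequence:

* **Breath segmentation** finds alternating extrema of the global
  (summed in-mask pixel) curve, pruning oscillations smaller than 10% of
  the curve's full excursion; the largest trough-to-peak rise is the SVC
  inspiration. Endpoints count as end-expiration candidates only — a
  recording truncated mid-slope cannot contribute a spurious
  end-inspiration.
* **Tidal variation (TV) image**: end-inspiration minus end-expiration,
  averaged over the complete pre-SVC tidal breaths; its pixel sum equals
  the global-curve difference exactly.
* **SVC normalization**: all impedance amplitudes can be scaled by
  `svc_volume_mL / dZ_svc`; shape indices are invariant, only reported
  units change.
* **Linearity**: Pearson r between spirometry volume (linearly
  interpolated onto EIT timestamps) and the global curve over the SVC
  segment (scope configurable to the whole recording), and the ratio of
  mean tidal TV to the SVC excursion.
* **Functional-lung ROI**: pixels reaching 20% of the TV maximum
  (config-exposed; the conventional functional-lung choice).
* **GI**: sum of absolute deviations from the ROI median TV, over the
  ROI TV sum; the median is taken over ROI pixels only, following the
  dominant convention of the GI literature.
* **CoV**: amplitude-weighted centroid along the ventral-dorsal axis in
  percent (0% ventral edge); row 1 of the image is ventral, column 1 the
  subject's right.
* **RVD-SD**: per-ROI-pixel time to reach 40% of the pixel's maximal
  inspiratory change across the SVC inspiration (the low-flow maneuver
  the delay definition assumes), by linear interpolation between frames,
  as percent of global inspiration time; the population SD over pixels
  summarizes temporal heterogeneity. Non-crossing pixels are excluded
  and counted.

Splits for the right/left and ventral/dorsal fractions are at the image
midlines — the methodology compares *regions*, not segmented anatomical
lungs.

## Device-agreement statistics

`run_study()` emulates the full study design on n synthetic subjects
(right-lung weight drawn uniformly from 0.45-0.55, other phantom
parameters fixed), producing per-subject, per-device, per-repetition
index rows, then:

* **Bland-Altman**: bias and 1.96 x SD limits of agreement of the
  repetition-1 device differences (sample SD, n-1).
* **Equivalence**: *paired* two-one-sided-tests (TOST) on the same
  differences — paired because both devices measure the same subjects;
  the p-value is the larger one-sided p. Margins are never part of the
  emulated methodology's record, so the default is 0.2 x the
  across-subject SD of the device-B values, always reported alongside p
  and overridable per index.
* **Repeatability**: per-subject percent variability
  `100 |m1 - m2| / mean(m1, m2)` within each device, summarized as
  mean ± SD.
* **Post-hoc power** of the paired TOST by the standard noncentral-t
  approximation, cross-checked against Monte-Carlo in the tests.

Calibration properties asserted by the test-suite: TOST type-I error at
the margin boundary stays within alpha + 2% over 5,000 replicates, and
the limits of agreement cover 93-97% of 10,000 simulated normal
differences.

## Bench QC

`channel_snr()` implements the sample-SD-over-mean SNR in dB with the
N-1 divisor exactly as the device-evaluation protocol states it, on
frame-level channel values (N = 1000 samples in the bench protocol);
the magnitude of the mean is used, since the sign of a channel voltage
is representation-dependent — the report carries a note to that effect.
`drift_metric()` compares first- and last-minute channel means across
the window (robust to noise, unlike instantaneous endpoints) and the QC
report takes the worst channel. The synthetic resistor-network recording
reproduces the bench setup nominally: 100 ohm per channel pair at 5 mA
gives 0.5 V per measuring pair, with configurable noise and drift.

## Problem sizes and determinism

The default test-suite uses the refinement-1 mesh (372 elements)
everywhere except the full-pipeline linearity check (refinement 2,
1472 elements); statistical calibration uses 5,000-10,000 replicates of
scalar statistics. Every stochastic step takes an explicit seed and
restores the caller's RNG state; equal seeds reproduce recordings
bit-exactly. The acceptance script derives its sub-seeds from a single
`--seed` argument.

## Known limitations

* 2D circular/elliptical domains only; no anatomical contours, no 3D
  effects, no electrode-plane obliquity.
* The forward-and-inverse pair shares one mesh (see above).
* Amplitude response of the reconstruction is uniform only to the extent
  the GREIT desired-image design achieves it; regional fractions inherit
  a small centre-ward bias that the recovery tests bound at the default
  geometry (right-fraction bias well under 0.02).
* The repeatability and agreement figures quantify noise-limited
  performance of the analysis chain, not human-measurement variability.
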