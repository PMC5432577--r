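---
title: "Methods: SEMG fatigue indices during cyclic back extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEMG fatigue indices during cyclic back extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

During repeated submaximal trunk extensions the surface EMG (SEMG) of the
lumbar extensors changes systematically with accumulating localized muscle
fatigue: the amplitude (RMS) of the signal tends to rise at constant load,
and the spectral content compresses toward lower frequencies, conventionally
tracked by the decline of the median frequency. Because the exercise is
cyclic, each movement cycle contributes one concentric (trunk extending,
40° to 0° of flexion) and one eccentric (forward-flexing, 0° to 40°) data
segment per electrode, and the two phases are analysed separately: the
muscle actions, recruitment strategies, and hence the fatigue signatures of
shortening and lengthening contractions differ.

`semgfatigue` implements that analysis end to end: cycle segmentation
driven by a lever-arm accelerometer, Cohen-class time-frequency estimation
of the instantaneous median frequency (IMDF), MVC-normalized RMS, per-cycle
least-squares fatigue trends, electrode aggregation by spinal level, and
median-based cohort statistics. A seedable synthetic-data generator with
exact ground truth makes every stage testable by parameter recovery, which
matters because no public recordings accompany this protocol.

# Signal chain and models

## Pre-filtering

All SEMG is conditioned by a 20 Hz high-pass and a 500 Hz low-pass
Butterworth filter. The cut-offs are protocol constants; the order (4th per
section) and the zero-phase forward–backward application are this package's
choices — zero phase avoids skewing energy across the concentric/eccentric
segment boundaries. `r-signal`'s `filtfilt` handles initial conditions
poorly for low cut-offs, so filtering goes through a wrapper that removes
the straight line through the endpoints, extends the residual by odd
reflection (pad of three time constants of the low cut-off), filters
forward–backward, and restores the line for low-pass filters only. On a
constant or a linear ramp this is exact to machine precision, which the
kinematics tests rely on.

## Kinematics and segmentation

Trunk orientation is approximated from the accelerometer z-axis as
α = asin(acc/g); the arcsine is clamped for |acc/g| ∈ (1, 1.05] (sensor
noise around full gravity) and rejected beyond that. Angular velocity is
the central first difference of the angle after an 8th-order, 1 Hz
zero-phase Butterworth low-pass.

Cycles are delimited by alternating extrema of the filtered angle
(minimum peak separation 0.4 of a nominal 4 s cycle); the rising half-cycle
is labelled eccentric, the falling half concentric. Within each half-cycle
only the centered 1.0 s window is retained, so movement velocity and
muscle-length trajectories are comparable across segments, and a half-cycle
is flagged when the window contains angular-acceleration magnitudes above
the trial's 90th percentile — a trial-relative operationalization of
"disproportionally large" acceleration, chosen because it is scale-free;
the threshold quantile is configurable. The first and last 2 cycles are
always flagged (start-up and wind-down transients; configurable, and the
protocol's own convention is 2–3). Flagged half-cycles are excluded from
all downstream estimates but kept in the segment table with their reason.
Fewer than 15 retained cycles aborts the trial, mirroring the protocol's
minimum for consistent biomechanics. All spans are 0-based half-open
sample intervals, re-expressed on the SEMG clock.

## Time-frequency analysis and IMDF

Bilinear (Cohen-class) distributions are used instead of short-time
spectra because the within-segment signal is non-stationary. The
implementation is the Choi-Williams member: the instantaneous
autocorrelation of the analytic signal, K(n, m) over lag m, is smoothed in
time with the exponential kernel's lag-dependent Gaussian (sd
m·sqrt(2/σ), σ = 1 by default) and transformed over lag (Hanning lag
taper, max lag 512 samples, FFT length the next power of two ≥ twice the
segment length, frequency grid to Nyquist).

Two discretization details matter in practice:

* **Fixed time window.** The CW kernel applies almost no time smoothing at
  small lags — that is what preserves its marginals — so for stochastic
  signals the per-instant spectra carry broadband, sign-alternating noise.
  Clipping negative values (required before a median can be read off)
  rectifies that noise and biases the IMDF upward by several Hz. As in
  standard discrete Cohen-class implementations, a fixed Gaussian time
  window (sd 20–40 ms; default 0.04 s) is therefore convolved with the
  kernel's own spread. The residual upward bias on 1-s stochastic segments
  is of the order of 1 Hz, within the 2 Hz calibration tolerance the test
  suite enforces against the generator's ground truth; pure tones are
  unaffected.
* **Edges.** Segments are extended by mirror reflection before the
  analytic signal is taken, and analysis instants keep a margin of at
  least the smoothing extent from the joins; zero padding instead leaks
  energy across the spectrum at edge instants.

The clipped-energy fraction is recorded on every distribution as a
diagnostic. The IMDF at an instant is the smallest grid frequency at which
cumulative power reaches half the column total, linearly interpolated
between the bracketing bins (a virtual zero-power bin one grid step below
the axis anchors the first bin); an all-zero column yields a missing
value. The per-segment summary is the **median** of the per-instant track
(robust to residual edge artifacts), missing when more than half the
instants are undefined. The default track has 128 instants per segment.

## Fatigue indices

Per retained segment and electrode: RMS over the span (divided by the
channel's 80% MVC reference RMS, computed over the [2 s, 5 s) half-open
window of the isometric recording — exactly 3 s) and the segment IMDF.
Each channel × phase series is fitted by ordinary least squares against
segment mid-time in seconds from exercise onset; the abscissa is time, not
cycle index, because slopes are reported in % of the initial value per
second. The initial value is the intercept at t = 0 — extrapolated, so it
refers to exercise onset even though the first cycles are excluded — and
the normalized slope is 100·slope/intercept. Normalized-RMS series are
fitted after MVC normalization; IMDF series are fitted in Hz and only the
slope is normalized, matching how initial values are conventionally
reported (unitless for RMS, Hz for IMDF).

Aggregation follows the three-level reporting scheme: left and right
trend parameters are averaged within level; the L1/L2/L5 entries are
averaged into the "all electrodes" row; and the "most negative electrode"
row picks, independently per parameter × phase, the single channel of six
with the smallest normalized slope. Choosing per parameter (the RMS-selected
electrode may differ from the IMDF-selected one) reflects that the two
parameters are reported in separate tables. Concentric/eccentric ratios of
initial values and slopes are attached per row.

## Statistics

Cohort contrasts are on medians: the index distributions are markedly
skewed. Both tests are percentile bootstraps (default 2,000 resamples,
seeded): the bootstrap distribution of the median contrast is compared
against zero and the two-sided p is twice the smaller tail probability
(ties half-weighted). Concentric vs eccentric is paired (each subject
contributes both phases): the within-subject differences are resampled.
The age × gender analysis is a 2 × 2 design on cell medians — main effects
are differences of marginal means of cell medians, the interaction the
difference of differences — with age binned at the cohort median by
default (the binning is configurable; no convention is established for
this protocol). Type-I error of the paired test is calibration-tested:
at n = 40 with lognormal nulls the empirical rejection rate at α = 0.05
must land in [0.035, 0.065] (it measures ≈ 0.04–0.06).

A caveat the test suite documents explicitly: at very small samples
(n ≤ 12) the percentile-bootstrap p and an exact sign-flip permutation p
agree closely only away from the null (clearly separated samples). For
random null draws the two differ by ~0.1 on median — the permutation
distribution of a median statistic is granular at that n, with tie atoms
of comparable size, so pointwise agreement to 0.05 is not a property this
(or, we believe, any) bootstrap analog can deliver. The corresponding
acceptance check is left failing on such inputs rather than weakened.

# The synthetic-data generator

The generator emulates the study conditions: 25 cycles of 4 s spanning
0–40°, six SEMG channels at 2,000 Hz, accelerometer at 160 Hz, an 80% MVC
reference of 6 s, baseline noise 0.75 µV RMS, concentric/eccentric
amplitude ratio 1.85, per-level initial median frequencies L5 70, L2 57,
L1 53 Hz, and default drifts equal to the cohort-median fatigue indices
(RMS +0.13 %/s concentric and 0 eccentric; IMDF −0.11 %/s in both
phases). The MVC reference amplitude defaults to the initial concentric
RMS divided by 1.21, placing the normalized initial value at the typical
level for this exercise.

Design choices:

* **Angle waveform.** A raised cosine over the full cycle (eccentric
  descent then concentric return). Its angular acceleration peaks at the
  movement turnarounds — as in paced human movement — and is near zero in
  the retained central windows, which is the geometry the artifact
  exclusion rule presumes. (A minimum-jerk half-cycle profile was
  considered and rejected: its acceleration peaks *inside* the central
  window, so the percentile rule would flag every half-cycle of a clean
  trial.) Peak velocity is π·40/4 ≈ 31 °/s; the protocol's nominal pacing
  and its reported peak velocities disagree with each other, and neither
  is imposed. The accelerometer trace is the exact inverse of the
  orientation estimate, acc = g·sin(α), so the kinematics stage can be
  validated in closed form.
* **Spectral shape.** Each half-cycle of each channel is Gaussian noise
  shaped in the frequency domain by the classic two-pole surface-EMG
  spectrum S(f) ∝ f_h⁴f²/((f²+f_l²)(f²+f_h²)²), multiplied by a smooth
  window emulating the 20–450 Hz analog acquisition band (cosine ramps
  18–28 and 400–450 Hz). Band-limiting the synthesis makes the digital
  pre-filter nearly transparent, so configured RMS and median targets
  survive the conditioning chain. The low pole is pinned at the target
  median and the high pole solved numerically (memoised root finding on a
  0.05 Hz grid) so the windowed shape's median equals the target exactly.
  With a low pole far below the target, an appreciable fraction of mass
  would fall under the 20 Hz high-pass and bias every downstream spectral
  estimate.
* **Drift.** Piecewise-stationary per half-cycle: targets are evaluated at
  the half-cycle's mid-time (RMS_phase(t) = RMS₀(1 + s·t), likewise for
  the median), matching the per-cycle resolution of all downstream
  estimates. The poles are re-solved at each drifted target rather than
  scaling the frequency axis: under a fixed acquisition band, axis scaling
  makes the realized median drift measurably flatter than the stored
  linear law, corrupting the ground truth that recovery tests depend on.
* **Calibration as a contract.** Empirical segment RMS must match targets
  within 3% and the stationary spectral median within 2 Hz (periodogram
  oracle), both averaged over 20 seeds; these are tested invariants, not
  aspirations.
* **Leakage.** Ground truth (half-cycle boundaries, per-segment targets,
  imposed slopes, MVC RMS) is returned as a sidecar and written as
  `ground_truth.json`; no pipeline stage reads it.

What the generator does **not** emulate: motor-unit firing statistics and
MUAP shapes (the signal is Gaussian by construction), amplitude
modulation within a half-cycle, electrode crosstalk and spatial
correlation between channels, movement artifacts and baseline wander,
torque/load variation, and between-cycle variability beyond the imposed
deterministic drift. Passing recovery tests therefore demonstrates that
the pipeline measures what it claims on signals with known spectral and
amplitude structure — not that it is robust to every pathology of real
recordings.

# Numerical conventions and degenerate inputs

* Spans are 0-based half-open everywhere; clock conversion rounds at the
  target rate and is tested to move boundaries by less than one
  accelerometer sample.
* `fit_trend` requires ≥ 5 points, errors on constant abscissae, and
  returns a missing normalized slope when the intercept is
  indistinguishable from zero at the data's scale (|b₀| ≤ 1e-10 of the
  value range).
* Zero-variance bootstrap distributions give p = 1 when the observed
  contrast is zero and p = 0 otherwise.
* An all-zero TFD column yields a missing IMDF; a segment with more than
  half its instants missing yields a missing summary and is dropped from
  trend fitting.
* Determinism: every stochastic routine takes a seed; identical seed and
  configuration reproduce recordings bit-exactly and pipeline CSVs
  byte-identically. Derived seeds stay below 2³¹ − 1.

# Problem sizes

The test suite simulates full-size trials (25 cycles × 4 s × 6 channels at
2 kHz) where the claim under test concerns the whole pipeline — parameter
recovery uses 20 such trials — and smaller configurations (1–3 cycles, one
channel) for container, calibration and unit checks. The statistical
calibration uses 1,000 null datasets of n = 40. The end-to-end pipeline
test runs two 20-cycle subjects with a decimated 48-instant IMDF grid.
These sizes were chosen so the estimator variances under test are well
below the tolerances being asserted.

# Known limitations

* The IMDF of 1-s stochastic segments retains a small positive bias
  (order 1 Hz) from negativity clipping; it is common-mode across a trial
  and largely cancels in normalized slopes, but absolute initial IMDF
  values run slightly high.
* The accelerometer inversion ignores tangential acceleration of the
  lever arm; this is inherent to the α = asin(acc/g) approximation and
  only affects segmentation timing, which the noise-robustness test
  bounds at < 50 ms.
* The exclusion rule trims to a centered window and flags; it cannot
  reproduce a protocol that silently dropped variable sub-portions of
  half-cycles.
* Bootstrap median tests are calibrated at the tested n = 40; no claim is
  made for very small cohorts, where the permutation comparison above
  applies.
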