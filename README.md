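# semgfatigue

Muscle-fatigue indices from surface electromyography (SEMG) of the lumbar
extensors during cyclic submaximal back-extension exercise.

During repeated trunk extensions at constant load, localized muscle
fatigue shows up in the SEMG as a rise in signal amplitude and a
compression of the spectrum toward lower frequencies. This package
implements the full analysis for the paced cyclic protocol (25 cycles of
~4 s, 0–40° of trunk flexion, six electrodes over multifidus at L5,
longissimus dorsi at L2 and iliocostalis lumborum at L1, both sides, with
a lever-arm accelerometer and an 80% MVC isometric reference per subject):

* **Segmentation** — trunk angle `α = asin(acc/g)` from the accelerometer
  z-axis; angular velocity via an 8th-order 1 Hz zero-phase Butterworth
  low-pass and first difference; cycles delimited by alternating angle
  extrema, the rising half labelled *eccentric*, the falling half
  *concentric*; a centered 1 s window retained per half-cycle, half-cycles
  with disproportionally large angular acceleration and the 2 edge cycles
  at each end excluded.
* **Amplitude** — per-segment RMS after 20–500 Hz zero-phase Butterworth
  band-passing, normalized by the channel RMS over seconds [2, 5) of the
  sustained 80% MVC contraction.
* **Spectrum** — Choi-Williams (Cohen-class) time-frequency distribution
  of the analytic signal, negative values clipped, and the instantaneous
  median frequency (IMDF): at each instant the frequency f* splitting the
  instantaneous spectrum's power in half; the segment value is the median
  of the per-instant track.
* **Fatigue indices** — for each electrode × phase, the least-squares line
  of the per-cycle values against time from exercise onset: the intercept
  is the *initial value*, and the slope, as % of the initial value per
  second, is the fatigue index. Electrodes are side-averaged per level,
  levels averaged into an "all electrodes" entry, plus a "most negative
  electrode" selection.
* **Statistics** — percentile-bootstrap median tests: paired one-way for
  concentric vs eccentric, two-way (age group × gender, cell-median
  contrasts) for the concentric/eccentric ratios.
* **Synthetic data** — a seedable generator producing recordings with
  exact ground truth (band-shaped Gaussian noise with controlled RMS and
  spectral-median drift, raised-cosine kinematics, MVC reference), so
  every stage is verified by parameter recovery; no external data needed.

It is written for biomedical-signal researchers who need a transparent,
tested reference implementation of this analysis or a harness to validate
their own.

## Worked example

Simulate one subject, segment, and compute its fatigue indices
(`analysis/01_simulate_trial.R` … `03_fatigue_indices.R` run exactly
this):

```r
library(semgfatigue)

cfg   <- synthetic_config(seed = 2026)          # study-condition defaults
trial <- simulate_subject(cfg, "EX01", age = 47, sex = "female")

kin  <- kinematics_trace(trial$cyclic$accel_z, trial$cyclic$accel_rate)
segs <- segment_cycles(kin, trial$cyclic$semg_rate)
mvc  <- mvc_reference(trial$mvc80)
agg  <- aggregate_subject(trial_trends(analyze_trial(trial$cyclic, segs, mvc)))
```

Printed summary of that run:

```
Segmented 25 cycles -> 21 retained after edge omission
  retained window 1.0 s per half-cycle; phase-label agreement with ground truth: 100%
Fatigue indices, all-electrode aggregate (imposed in parentheses):
  normalized RMS initial: conc 1.20, ecc 0.65 -> ratio 1.84 (1.85)
  RMS slope  %/s: conc +0.115 (+0.13), ecc -0.017 (+0.00)
  IMDF slope %/s: conc -0.116 (-0.11), ecc -0.110 (-0.11)
  most negative electrode (IMDF, concentric): L5_left at -0.193 %/s
```

Reading: of 25 cycles, the 2 at each end are dropped and all 21 remaining
pass the acceleration screen. The concentric phase runs at ~1.2× the 80%
MVC amplitude and the eccentric at ~0.65×, an amplitude ratio of 1.84
against the imposed 1.85; amplitude climbs during concentric work
(+0.115 %/s) while the spectrum compresses in both phases (−0.11 %/s),
each recovered within the estimator's precision from a single trial.

`analysis/04_cohort_analysis.R` repeats this for 24 simulated subjects and
emits the cohort tables (`results/table_phase_comparison.csv`,
`results/table_ratio_age_gender.csv`):

```
All-electrode cohort medians (Q25; Q75):
  RMS initial (rel. 80% MVC)   conc   1.205 (1.194; 1.214)  ecc   0.653 (0.648; 0.659)  p = 0.000
  RMS slope (%/s)              conc   0.128 (0.109; 0.140)  ecc  -0.004 (-0.015; 0.002)  p = 0.000
  IMDF initial (Hz)            conc  62.011 (61.623; 62.414)  ecc  61.697 (61.387; 62.082)  p = 0.306
  IMDF slope (%/s)             conc  -0.104 (-0.120; -0.096)  ecc  -0.098 (-0.109; -0.084)  p = 0.160

  conc/ecc initial-RMS ratio: 1.85 (1.83; 1.87); age p = 0.245, gender p = 0.158, interaction p = 0.395
```

The cohort reproduces the qualitative pattern of interest: amplitude rises
significantly during concentric but not eccentric work, spectral
compression is equally present in both phases, and the amplitude ratio
shows no age or gender effect (none was imposed).

## Layout

```
R/, src/            implementation (R + one Rcpp kernel)
tests/testthat/     unit, property and acceptance tests
analysis/           numbered narrative drivers over the package
scripts/acceptance.R
vignettes/semg-fatigue-methods.Rmd   the methods account
```
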