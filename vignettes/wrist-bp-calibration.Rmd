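---
title: "Calibrating wrist-cuff blood pressure devices against intra-arterial references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating wrist-cuff blood pressure devices against intra-arterial references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcal)
```

## The problem

Automatic cuffs — and wrist cuffs in particular — are licensed against manual
auscultatory readings, not against the intra-arterial pressures that are the
physiologic ground truth. A device that systematically under-reads systolic
pressure leaves hypertensive patients untreated (a *treatment gap*); one that
over-reads diastolic pressure invites overtreatment. `wristcal` implements
the analysis chain of a catheterization-lab validation study: simultaneous
wrist-cuff and intra-arterial (right radial and ascending aortic) readings
are collected under a two-day protocol, the device is recalibrated to the
direct pressures by jackknife leave-one-out regression, agreement is
summarized by Bland-Altman statistics with an absolute-mean-difference bias,
and hypertension calls are cross-tabulated against guideline thresholds.

No patient-level data are redistributed with such studies, so the package
ships a seeded synthetic-data generator that reproduces the *statistical
structure* the analysis assumes. Every downstream stage is exercised, and
tested, against that generator.

## The synthetic cohort and what it emulates

`simulate_cohort()` draws patient profiles whose marginal distributions match
a typical elective-catheterization cohort: age 62 (SD 9, range 43–77) years,
BMI 30.6 (SD 5.7), 75% male, 75% already diagnosed hypertensive, central
aortic systolic pressure 133.4 (SD 22.0, range 96.7–179.3) mmHg and aortic
diastolic 67.4 (SD 8.7, range 50.6–85.1) mmHg. Two implementation choices
matter:

* **Recentred truncation.** Pressures are drawn from range-truncated
  normals. Truncating an N(133.4, 22²) to [96.7, 179.3] shifts its mean up
  by about +1.25 mmHg, so the latent location is recentred by root finding
  until the *post-truncation* mean equals the configured mean. The configured
  means are sample means of a real finite cohort, and that is what the
  generator should reproduce.
* **Stratified hypertension flag.** Exactly `round(n × prevalence)` patients
  are flagged hypertensive, so a 20-patient default cohort is always 15/20 =
  75%. The flag describes a fixed cohort composition, not a sampling model,
  and it is deliberately independent of the drawn pressures (a simplification
  real data would not show).

Peripheral (radial) pressure exceeds central pressure through pulse-pressure
amplification: each patient carries a radial-minus-aortic systolic
augmentation offset, mean 12.3 mmHg with a between-patient SD of 10 mmHg,
and a near-zero diastolic offset (mean −1.2 mmHg, SD 1.5 mmHg — the SD is a
package choice; only the means are pinned by the cohort description).

## Beat-to-beat variability

Intra-arterial pressure drifts by roughly 20 mmHg systolic / 10 mmHg
diastolic over a few minutes. `simulate_beat_series()` models each channel
as a stationary AR(1) process around the site mean, lag-1 correlation 0.7 at
a 10 s sampling step — the simplest process with a smooth, mean-reverting
multi-minute swing. The marginal SD is set so the *expected range* of a
25-sample (240 s) series equals 20 mmHg systolic / 10 mmHg diastolic. The
scaling constant — the expected range of a standardized AR(1)(0.7) at n = 25
— was estimated once by Monte Carlo (4×10⁵ replicates) as 3.3897 (SE 0.0012)
and is frozen in the package; the default marginal SDs are therefore
20/3.3897 ≈ 5.90 and 10/3.3897 ≈ 2.95 mmHg.

Each reading is acquired over a 60 s window (7 samples at 10 s). Simultaneity
of a wrist/intra-arterial pair means *the identical underlying beat window*:
the radial window is the aortic window plus the patient's augmentation
offsets, the intra-arterial reference is the exact window mean, and the
device reads the same window through its transfer model.

## The stand-in device

The real device's waveform-to-pressure algorithm is proprietary; the package
substitutes two documented components:

* An oscillometric front end (`oscillometric_envelope()`,
  `fixed_ratio_estimate()`): a Gaussian-kernel oscillation envelope centred
  at each beat's mean arterial pressure (MAP = diastolic + pulse pressure/3)
  with width half the pulse pressure, and the classical maximum-amplitude /
  fixed-ratio back end with default ratios (0.55, 0.85) — standard values in
  the oscillometric literature. These are exercised and tested on analytic
  envelopes.
* A direct transfer model (`device_reading()`): reported pressure =
  intercept + slope × window-mean pressure + Gaussian noise. This is what
  the study simulator uses. The reported per-reading SD propagates the
  within-window beat variance through the device gain and adds the device
  noise in quadrature, `sd = sqrt(slope² · var(beats) + noise²)` — the
  measurement-uncertainty reporting that distinguishes this class of device.

The default wrist model (systolic −5 + 0.95×true, noise SD 6; diastolic
+14 + 1.0×true, noise SD 4) is *illustrative*: it was chosen so that
pre-calibration absolute mean differences land in the 10–16 mmHg regime
reported for factory-calibrated devices, and it is a configuration value, not
a claim about any product. A simulated device never emits systolic ≤
diastolic: the diastolic value is capped at systolic − 5 mmHg (a minimal
pulse-pressure floor), which a strongly miscalibrated transfer model would
otherwise occasionally violate for low-pressure patients.

Auscultatory observers (`auscultatory_reading()`) add Gaussian noise to the
window mean and round to the nearest 2 mmHg, half away from zero — the
sphygmomanometer terminal-digit convention; double-observer mode averages two
independent observers.

## Protocol encoding

Eligibility (`eligibility_filter()`): age ≥ 19, wrist circumference within
13.5–23 cm inclusive, and none of the clinical exclusion flags. The bilateral
screen (`bilateral_equality_screen()`) averages the two observers per arm and
passes iff the between-arm differences are within ±10/±5 mmHg, inclusive; all
"within ±x" bounds in the package are read as closed intervals. The arm-mean
comparison (rather than observer-wise) was chosen because the screen's
purpose is a per-arm pressure estimate, and two observers are averaged for
precision.

Day 2 produces ten readings per patient: 2 conditioning wrist readings
(always discarded), 2 wrist + 2 intra-radial simultaneous readings, 2 wrist +
2 intra-aortic simultaneous readings. `assemble_day2_pairs()` pairs wrist and
reference readings by order index within stage — the generator guarantees
that readings sharing an order index share the beat window, and the pairing
rule is stated explicitly because raw tables carry no other simultaneity key.

## Jackknife calibration and its estimand

`fit_affine()` regresses the reference on the device value by ordinary least
squares; affine (offset + gain) is the minimal family expressing both error
modes, with an offset-only family as a configuration point.
`jackknife_calibrate()` holds each of the N pairs out in turn, fits on the
remaining N−1, and predicts the held-out device value; downstream agreement
consumes *only* held-out predictions, so post-calibration agreement is an
honest out-of-sample quantity. The deployed model (for reuse on new readings,
e.g. the independent archive) is the full-data fit.

One point deserves emphasis: **with a noisy device, the least-squares
calibration slope is not the inverse of the device gain.** The calibration
estimand is the best affine predictor E[reference | device]. Because the
device value carries measurement noise, that slope is attenuated relative to
1/gain (regression to the mean); against the aortic reference the
patient-level augmentation acts as further noise and attenuates it more.
This is a property of the estimand, not an estimator defect — and it is the
*correct* calibration: applying the literal inverse transfer model to a noisy
reading would inflate its error. The test suite verifies that deployed
coefficients, averaged over replicated studies, recover the analytically
derived population coefficients (truncated-normal patient variance +
augmentation variance + AR(1) window-mean variance entering the attenuation
formula) to within 0.05 in slope and 2 mmHg in intercept.

Calibrated per-reading SDs are scaled by the (positive) slope, the affine
uncertainty-propagation rule.

## Agreement conventions

`bland_altman()` reports both the signed family (mean difference, SD, limits
of agreement mean ± 1.96 SD) and the absolute family (mean |d| with its own
SD) — the latter is the "bias" convention of intra-arterial validation work,
and `absolute_mean_difference ≥ |signed_mean_difference|` always. The paired
p-value is a two-sided paired t-test by default (a Wilcoxon signed-rank
alternative is exposed); with zero variance, p = 1 when all differences are 0
and p = 0 otherwise, by convention. The a-priori validity rule
(`validity_check()`) is 10 mmHg systolic / 5 mmHg diastolic, inclusive,
against a required fraction of 1 by default. Pairs from the same patient are
treated as independent throughout, as is conventional in this literature even
though it understates the standard errors of pooled statistics; a
repeated-measures correction of the limits of agreement is a noted extension,
not implemented.

`improvement_metrics()` reports percentage improvements unrounded, plus a
display value rounded half away from zero. Published improvement figures
are typically computed on unrounded data and then rounded; the package does
not attempt to reproduce rounded-input arithmetic beyond the worked examples
in its tests.

## Threshold classification and the Fisher direction

`classify_reading()` applies inclusive OR rules; the shipped threshold sets
are CHEP (≥ 135 systolic or ≥ 85 diastolic — the home-monitoring
confirmation threshold) and SPRINT (≥ 120 systolic, no diastolic criterion).
The treatment gap is b/(a+b): the fraction of reference-hypertensive
measures the method calls normotensive (denominator = reference positives;
equivalently 1 − sensitivity).

`method_comparison()` reports two one-tailed Fisher exact p-values, and the
distinction is statistical, not cosmetic. `fisher_p` conditions on the
margins of the paired ref × method cross-tab ("less" direction); because a
uniform call-rate deficit moves the *margins*, this test measures
association, and a cuff that under-reads every patient by the same amount
can still show perfect association. `fisher_p_rates` therefore also tests
the unpaired comparison of positive-call *rates* between the method and the
reference (one-tailed, "method calls fewer positives") — the comparison that
actually flags an under-reading cuff. Users interested in the treatment gap
should read `treatment_gap` and `fisher_p_rates` together.

## Numerical and degenerate-input choices

* Truncated draws: inverse-CDF sampling; recentring by `uniroot` to 1e-10.
* Envelope estimation: the MAP is the grid argmax (1 mmHg default grid);
  ratio crossings are located by linear interpolation between grid points;
  a monotone envelope or a crossing outside the grid is an error.
* Zero-variance device values make the affine fit degenerate and error out;
  the jackknife requires N ≥ 3.
* Fisher tail sums are clamped to 1 against floating-point overshoot;
  degenerate margins give p = 1 by convention.
* All `simulate_*` functions are pure functions of (inputs, seed); passing
  `seed = NULL` uses the ambient RNG stream so that compound generators can
  seed once at the top.

## Problem sizes in the test suite

The statistical guarantees are verified on 200 replicated 20-patient studies
(about two minutes in total): deployed-coefficient recovery against the
analytic population values; post-calibration held-out absolute mean
difference smaller than pre-calibration in ≥ 95% of replicates on the radial
path, where the default device bias is −12.3 mmHg systolic / +14 mmHg
diastolic; and a strictly positive treatment gap in ≥ 95% of cohorts for a
−12 mmHg upper-arm cuff against the aortic reference. Oracle equivalences
(jackknife vs brute-force leave-one-out, Fisher vs full hypergeometric
enumeration) run on hundreds of random small instances. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances.

## What passing tests do and do not show

The generator emulates marginal cohort distributions, smooth intraphysiologic
drift, patient-level augmentation, device miscalibration with reported
uncertainty, and observer rounding. It does not emulate waveform morphology,
arrhythmia or tremor artifacts, pressure-dependent (nonlinear) device error,
correlation between the hypertension flag and the drawn pressures, or
drift between the two study days. Green tests therefore establish that the
*analysis chain* is correct and that its statistical guarantees hold under
the stated data-generating process — not that any particular physical device
is accurate. The magnitude of the simulated treatment gap, in particular,
depends strongly on how the configured upper-arm bias interacts with the
threshold's position in the pressure distribution and should not be read as
a clinical estimate.
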