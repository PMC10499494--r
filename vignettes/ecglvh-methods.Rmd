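---
title: "Methods: automated voltage criteria for LVH detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated voltage criteria for LVH detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglvh)
```

## The problem

Left ventricular hypertrophy (LVH) — pathologically increased LV mass, most
often from chronic pressure overload or inherited cardiomyopathy — carries
prognostic weight, and the ECG remains the cheapest screen for it. Classical
voltage criteria combine R- and S-wave amplitudes from specific leads against
fixed cutoffs. This package automates four of them end to end, from raw
12-lead waveforms to binary calls and evaluation statistics, so that the
criteria can be studied, compared and stress-tested on data with known ground
truth.

The reference standard is echocardiographic: LV mass from linear
end-diastolic measurements, indexed to body surface area (LVMI), with
sex-specific cutoffs.

## The criteria

All amplitudes are magnitudes in mV relative to an isoelectric baseline;
`S(V1)` denotes the S-wave depth in lead V1, `R(V5)` the R-wave height in V5.
Display thresholds assume the conventional calibration of 10 mm per mV, so
20 mm = 2 mV; `mm_to_mv()` performs the conversion once at configuration
time and everything downstream is mV.

* **Adjacent precordial overlap (Witteles–Somani, WS).** For each adjacent
  precordial pair, `S(V_i) + R(V_(i+1))`, `i = 1..5`. Positive when the sum
  *exceeds* 20 mm (strict inequality — 2.000 mV exactly is negative). The
  visual correlate is overlap of QRS complexes of neighbouring chest leads on
  a standard display.
* **Sokolow–Lyon.** `S(V1) + R(V5)` and `S(V1) + R(V6)`; positive at
  ≥ 35 mm.
* **Cornell.** `R(aVL) + S(V3)`; positive above 28 mm (men) / 20 mm (women).
* **Peguero–Lo Presti.** Deepest S in any available lead plus `S(V4)` (V4
  may supply both terms); positive at ≥ 28 mm (men) / 23 mm (women).

The comparator cutoffs are the criteria's published values and are exposed in
`threshold_config()`. Unknown sex falls back to the stricter (male) cutoff of
sex-specific criteria, with a warning — a conservative choice that cannot
inflate positivity.

### Per-ECG aggregation: MMCV

A criterion produces one value per beat per lead combination. The ECG-level
statistic is the **maximum over combinations of the median across beats**
(MMCV): the median suppresses ectopy and measurement outliers beat-to-beat,
the maximum preserves the criterion's "any pair qualifies" semantics. The
binary call and the ROC score are both computed from MMCV, so the two are
internally consistent by construction. Even beat counts average the middle
two values; MMCV is invariant to beat reordering and duplication and monotone
in every per-beat value.

### Sex-adjusted WS mode

A 10 mm (two large boxes) sex offset is available for the WS threshold. The
direction is configurable: the default lowers the female threshold to 10 mm,
which raises sensitivity in women — consistent with the adjustment's intended
effect — while `ws_adjust_direction = "raise_male"` raises the male threshold
to 30 mm instead. Both directions are implemented because either reading of
"adjusting the threshold by sex by 10 mm" is defensible; the choice is
explicit in the configuration rather than hidden.

## QRS detection

Beats are found once per ECG on a cross-lead **complex lead**: per lead, a
moving average spanning one power-line period (50 Hz default), a 28 ms moving
average (muscle noise), the absolute centered difference, and a 40 ms moving
average, summed over leads. Detection scans this channel with three adaptive
thresholds combined as `M + F + R`:

* **M** (steep slope): seeded at 0.6 × the complex-lead maximum of the first
  5 s; after each detection the buffer of the last five steep-slope values is
  updated (new values capped at 1.5× the previous to resist artifact spikes)
  and M decays linearly to 0.6 of its value between 0.2 s and 1.2 s after
  the beat.
* **F** (integrating): drifts every sample by the difference between the
  maximum over the trailing 50 ms and the maximum over a 50 ms window lagged
  300 ms, divided by 150 — it tracks the recent noise floor.
* **R** (beat expectation): zero until two thirds of the mean of the last
  five RR intervals has elapsed, then falls linearly to −0.3 M, lowering the
  combined threshold when a beat is overdue.

A 200 ms refractory period follows each detection; the fiducial is the
complex-lead maximum of the detection region. Every constant lives in
`christov_params()`. All three thresholds scale with the signal, so detection
is invariant to global amplitude scaling — a property the tests check
directly at factors 0.5 and 2.

Edge policy: filters use reflection padding and the first and last 0.5 s are
ineligible for fiducials, which keeps every measurement window inside the
record. A flat record returns an empty beat set flagged `LOW_SIGNAL` rather
than an error.

## Amplitude measurement

The baseline for each beat and lead is the median of the PR segment (120 to
60 ms before the fiducial); if that window falls off the record the lead-wide
median is used and flagged. Within the QRS window (−60 to +80 ms around the
fiducial), the R amplitude is the maximal positive deviation above baseline
and the S amplitude the maximal deviation below, clipped at zero. This
*extremal-deviation* definition (rather than sequence-ordered Q/R/S
labelling) is exactly what all four criteria consume, and it collapses
RSR′/QS ambiguities safely. Consequences worth knowing: adding a constant to
a lead changes nothing, scaling a lead by k scales both amplitudes by k, and
flipping a lead's polarity swaps R and S.

Beats whose measurement window crosses a record edge are dropped with a
message, never padded — padding would fabricate amplitudes.

**QRS duration** (used only for the `WIDE_QRS` quality flag at > 120 ms, a
proxy for bundle-branch block and paced rhythms when machine interpretation
statements are unavailable) is the width of the complex-lead region around
the fiducial above 10% of its beat-local peak, minus half the joint span of
the centered differencing and the final 40 ms moving average (≈ 22 ms at
500 Hz). The subtraction compensates the broadening that the filter chain
adds to any pulse: with it, the default ≈ 90 ms morphology measures ≈ 96 ms
and a 1.8×-widened one ≈ 142 ms, on opposite sides of the flag threshold
with balanced margins. The flag is advisory; only `TOO_FEW_BEATS` (< 3
beats) aborts an analysis, and `override_qc = TRUE` overrides even that.

## The synthetic generator

`generate_ecg()` builds each lead as a sum of five Gaussian waves (P, Q, R,
S, T) per beat plus sinusoidal baseline wander and white noise — an
ECGSYN-style simplification with independent per-lead amplitudes. The default
template mimics normal R-wave progression (deep S in V1–V2, transition at
V3–V4, tall R in V5–V6) with 60 bpm, 10 ms RR jitter, 0.02 mV noise and
0.05 mV wander at 0.33 Hz; beats live in `[0.5 s, duration − 0.5 s]`, the
detector's eligible zone. Ground truth records the noise-free fiducials and
per-beat, per-lead R/S amplitudes.

`generate_cohort()` plants a monotone LVMI–voltage relationship: LVMI is
drawn per class (defaults Normal(130, 20) for LVH, Normal(80, 15) otherwise,
truncated at 30 g/m²), and `voltage_effect` (default 0.01 mV per g/m²)
shifts the S amplitudes of V1–V3 and R amplitudes of V4–V6 by
`voltage_effect × (LVMI − 100)` plus 0.05 mV per-lead amplitude noise,
clamped so signs are preserved. Class-conditional draws are additionally
truncated to the class's side of the sex-specific cutoff, so the LVH label
equals the planted class and `lvh_prevalence` is the exact label prevalence.
Each subject's RNG stream derives from `(seed, subject index)`, so adding or
removing subjects never reshuffles the others.

What the generator does **not** emulate: realistic torso physics (amplitudes
are independent per lead, not projections of one dipole), arrhythmia,
bundle-branch morphologies beyond width scaling, electrode artifacts, or the
population correlation structure between sex, body habitus and voltage.
Passing tests on this generator therefore demonstrate that the pipeline
measures what the generator planted — algorithmic correctness, calibration of
the statistics, and monotone recovery of a planted mass–voltage link — not
clinical performance on hospital ECGs, which published work finds far more
modest for every voltage criterion.

## Echo reference

`devereux_mass()` implements
`0.8 × 1.04 × [(IVSd + LVIDd + PWTd)³ − LVIDd³] + 0.6` grams, BSA defaults
to Mosteller (`sqrt(height × weight / 3600)`; Du Bois selectable), and LVH is
`LVMI > cutoff(sex)`, strict. The default cutoffs are 95 g/m² (male) /
115 g/m² (female); because standard guidelines orient the cutoffs the other
way, `lvh_cutoffs("guideline")` provides the transposed preset
(115 male / 95 female). Both are plain configuration.

## Evaluation statistics

Confusion metrics use the Haldane–Anscombe 0.5 correction for the odds ratio
when a cell is zero (flagged). McNemar is computed without continuity
correction — `chi² = (b − c)² / (b + c)` — with an exact binomial p-value
when `b + c < 25` (small synthetic fixtures land here) and `chi² = 0, p = 1`
for the fully concordant degenerate case. The ROC sweep runs over observed
unique scores plus ±Inf endpoints with ties grouped at one threshold step;
its trapezoidal area equals the Mann–Whitney statistic
`P(score⁺ > score⁻) + ½ P(tie)`, which the tests verify against brute-force
pair counting and against an independent ROC implementation (pROC).
Confidence intervals are not emitted by default; a seeded bootstrap
(`auroc_ci()`, 1000 resamples) is available for AUROC.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise cohorts of 200 records of
10 s at 500 Hz — about 1,900 beats per cohort — which resolves beat-level
sensitivity/PPV at the 0.99 level and AUROC to a few points while keeping a
full run in minutes on one core. Tolerances: amplitude recovery is asserted
at 0.05 mV against ground truth (the dominant error is wave-overlap between
neighbouring Gaussians, ~0.01 mV, plus one-sample peak quantization);
beat matching uses a 75 ms window; MMCV and AUROC are checked against
exhaustive oracles to machine precision. WFDB output quantizes at
1000 ADU/mV (0.0005 mV), far below every tolerance.

## Known limitations

* The Christov constants are the published reference values tuned for human
  resting ECGs; very low sampling rates (< 100 Hz) are rejected outright.
* QRS duration is a flag-grade estimate, not a delineation; it inherits the
  complex lead's smoothing and should not be used for interval reporting.
* The WS sex-adjustment direction and the echo cutoff orientation each have
  two defensible readings; both are implemented and the defaults are stated
  above rather than silently chosen.
* Criteria combination search, repolarization features (ST depression,
  T-wave inversion, left atrial enlargement) and survival modelling are out
  of scope; the cohort manifest carries the columns a user would need to fit
  survival models elsewhere.
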