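# ecglvh

Automated ECG voltage criteria for left ventricular hypertrophy (LVH)
detection, with a synthetic 12-lead generator for end-to-end validation.

LVH — increased left-ventricular mass, typically from chronic pressure
overload or cardiomyopathy — is screened on the ECG with voltage criteria
that sum R- and S-wave amplitudes from specific leads. `ecglvh` implements
the adjacent-precordial-overlap criterion (Witteles–Somani): for each
adjacent chest-lead pair,

    WS_i = S(V_i) + R(V_(i+1)),   i = 1..5,

positive when the sum exceeds 20 mm (2 mV at the standard 10 mm/mV
calibration) — the visual correlate is overlapping QRS complexes in
neighbouring precordial leads. Alongside it: Sokolow–Lyon
(`S(V1)+R(V5 or V6) ≥ 35 mm`), Cornell (`R(aVL)+S(V3) > 28/20 mm` men/women)
and Peguero–Lo Presti (`S_deepest+S(V4) ≥ 28/23 mm`). Each criterion is
computed per heartbeat and aggregated per ECG as the **maximum over lead
combinations of the median across beats (MMCV)**, which serves as both the
binary call statistic and the ROC score.

The toolchain covers the full path from waveform to verdict:

* **I/O** — WFDB (header + format-16 signal) and a plain CSV dialect, all
  amplitudes in mV, leads addressed by name.
* **QRS detection** — the Christov adaptive-threshold detector on a filtered
  cross-lead complex lead (steep-slope M, integrating F, beat-expectation R
  thresholds, 200 ms refractory).
* **Measurement** — per-beat, per-lead R/S magnitudes against a PR-segment
  baseline; QRS-width quality flag.
* **Reference standard** — Devereaux LV mass
  `0.8·1.04·[(IVSd+LVIDd+PWTd)³ − LVIDd³] + 0.6` g, indexed to Mosteller or
  Du Bois BSA, with sex-specific LVMI cutoffs.
* **Evaluation** — confusion metrics, McNemar agreement, ROC/AUROC
  (Mann–Whitney-exact tie handling), Pearson correlation with LVMI.
* **Synthetic cohorts** — Gaussian-wave 12-lead records with known beat
  times and amplitudes, plus cohorts with a planted LVMI–voltage slope, so
  every stage is testable without clinical data.

## Worked example

```r
library(ecglvh)

ge <- generate_ecg(seed = 42, sex = "male")   # 10 s, 12 leads, 500 Hz
calls <- evaluate_record(ge$record)
print(calls)
#> <lvh_calls> synth (9 beats)
#> <criterion_result> WS: MMCV 2.283 mV > 2.000 mV -> POSITIVE
#> <criterion_result> SOKOLOW_LYON: MMCV 2.610 mV <= 3.500 mV -> negative
#> <criterion_result> CORNELL: MMCV 1.257 mV <= 2.800 mV -> negative
#> <criterion_result> PEGUERO_LO_PRESTI: MMCV 1.828 mV <= 2.800 mV -> negative
```

The WS MMCV of 2.283 mV means that, for the best adjacent pair, the median
over the record's nine beats of `S(V_i)+R(V_(i+1))` exceeds the 2 mV (20 mm)
cutoff, so this ECG is WS-positive; the other criteria stay under their
cutoffs on the same beats. The echo side:

```r
lvh_label(ivsd_cm = 1.3, lvidd_cm = 5.6, pwtd_cm = 1.2,
          height_cm = 182, weight_kg = 95, sex = "male")
#> <lvh_label> mass 296.6 g, BSA 2.19 m2, LVMI 135.4 g/m2 > 95 -> LVH
```

Cohort-scale runs go through `run_simulate()` / `run_analyze()` /
`run_evaluate()` or the equivalent CLI
(`inst/cli/ecglvh simulate|analyze|evaluate`), producing calls CSVs,
per-record JSON and per-criterion evaluation reports.

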