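# vtscreen

Identify ventricular-tachycardia (VT) patients from the **sinus-rhythm**
portions of long-term Holter ECG recordings.

VT — three or more consecutive ventricular complexes at > 100 b.p.m. — is
only documented when an episode is captured on a monitor. Between episodes,
however, VT patients tend to differ from non-VT patients: more premature
ventricular contractions (PVCs), a more fragmented inter-beat (RR) interval
series, and more variable beat morphology. `vtscreen` implements a complete,
tested pipeline that exploits this:

1. **Pre-processing** — zero-phase 2nd-order IIR band-pass (0.67–100 Hz)
   plus 50 Hz notch; splitting into 30-minute windows.
2. **Signal quality** — the beat-agreement index **bsqi**: F1 of the
   one-to-one matching between two independent QRS detectors
   (Pan–Tompkins-style energy detector and a curve-length detector),
   maximised over leads. Windows with bsqi ≤ 0.8 are excluded; recordings
   with fewer than six high-quality windows (per 24 h; scaled linearly for
   shorter recordings) are dropped; windows containing annotated VT events
   are excluded so the classifier only ever sees sinus rhythm.
3. **Beat analysis** — fiducial delineation (QRS on/offset by sustained
   slope thresholds, T end by the tangent method, P detection) and a
   rule-based five-class beat classifier (N/S/V/F/none) built on QRS width,
   prematurity and template correlation.
4. **Features** — 23 HRV features per window (time domain; the
   heart-rate-fragmentation indices PIP/IALS/PSS/PAS; Lomb–Scargle band
   powers; Poincaré, sample entropy, DFA) and 115 morphological features
   (22 waveform measures × {mean, median, min, max, IQR} + five beat-class
   ratios), plus 4 patient-information (PI) covariates.
5. **Classification** — gradient-boosted trees (xgboost) with mRMR feature
   selection, tuned by sequential model-based search under 4-fold
   patient-disjoint inner cross-validation; 10 outer train/test repeats;
   patient score = **median** window probability; reported metric =
   mean ± SD patient-level AUROC over the repeats.
6. **Evaluation** — Mann–Whitney feature screening at P < 0.05 on
   per-recording values, AUROC with brute-force-verified tie handling,
   pooled ROC curves with IQR envelopes.

Because no Holter database with VT labels is openly deposited, the package
ships a **synthetic cohort generator** (`cohort_spec()`, `simulate_cohort()`)
that emulates the statistical structure the analysis assumes — class-dependent
PVC burden and RR fragmentation, Gaussian-bump beat morphology with wide
inverted ventricular complexes, noise episodes, injectable VT runs — with
full ground truth at every stage. All class effects scale with a single
`effect_size_scale` knob (0 = null cohort), and patient information is
class-independent by design, providing a built-in negative control.

## Worked example

Simulate a small labelled cohort, run the full chain, and evaluate two
model variants:

```r
library(vtscreen)

spec <- cohort_spec(n_c0 = 30, n_c1 = 12, duration_hr = 0.5, fs = 128,
                    seed = 5)
cfg  <- validate_config(list(min_good_windows = 1))   # 1 window per 0.5 h
proc <- simulate_and_process(spec, cfg)

str(proc$manifest)
#> List of 7
#>  $ windows_total                 : int 42
#>  $ windows_retained              : int 32
#>  $ windows_excluded_quality      : int 0
#>  $ windows_excluded_vt           : int 6
#>  $ windows_in_excluded_recordings: int 4
#>  $ recordings_total              : int 42
#>  $ recordings_excluded           : int 4

plan <- make_splits(unique(proc$features[c("patient_id", "class_label")]),
                    outer_repeats = 2, seed = 3)
ev <- vt_evaluate(proc$features, variants = c("HRV+MOR", "PI"),
                  plan = plan, search_iterations = 6, seed = 9)
ev
#> Patient-level test AUROC (mean ± SD over outer repeats):
#>   HRV+MOR      0.917 ± 0.118  (2 repeats)
#>   PI           0.583 ± 0.589  (2 repeats)
```

On this small cohort the HRV+MOR variant separates the classes well (the
planted ten-fold PVC-burden shift is strong), while the PI-only variant
hovers at chance — patient
information carries no class signal by construction. Feature screening
shows what drives the discrimination:

```r
head(mann_whitney_screen(proc$features)[, c("feature", "p_value")], 3)
#>      feature      p_value
#> 1     Vratio 0.0006139054
#> 2 DFA_alpha1 0.0008950435
#> 3        PAS 0.0010766329
```

`Vratio` (the PVC fraction per window) and the irregularity-sensitive HRV
features dominate, mirroring the physiology planted in the generator. `plot(ev)`
draws the pooled ROC curves with interquartile envelopes.

A thin command-line wrapper is installed with the package
(`system.file("cli", "vtscreen.R", package = "vtscreen")`) with `simulate`
and `run` subcommands over YAML configs; `write_wfdb()` exports recordings
as WFDB records with CSV/JSON ground-truth sidecars.

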