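---
title: "Screening for ventricular tachycardia from sinus-rhythm Holter ECG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for ventricular tachycardia from sinus-rhythm Holter ECG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ventricular tachycardia (VT) — three or more consecutive ventricular-origin
complexes at a rate above 100 b.p.m. — is usually documented only when an
episode happens to be captured. The question this package addresses is
whether a patient who *has* VT episodes can be recognised from the
*sinus-rhythm* portions of a long-term (Holter) ECG alone. The working
physiological hypothesis is that VT patients differ even between episodes:
they carry a higher burden of premature ventricular contractions (PVCs),
their inter-beat (RR) interval series is more fragmented (frequent
acceleration/deceleration reversals), and their beat morphology is more
variable.

`vtscreen` implements the full analysis chain as a reusable pipeline:
quality-gated 30-minute windowing, engineered heart-rate-variability (HRV)
and morphological (MOR) features, minimum-redundancy maximum-relevance
(mRMR) feature selection with gradient-boosted trees under patient-disjoint
nested cross-validation, and per-patient aggregation by the median window
probability. Because no suitable Holter database with VT labels is openly
deposited, the package also ships a synthetic cohort generator that encodes
exactly the statistical structure the analysis assumes, with complete
ground truth for every stage.

## The synthetic cohort generator

Each patient is a draw from class-conditional parameter distributions
(`cohort_spec()`, `sample_cohort()`). All class differences are location
shifts scaled by a single knob, `effect_size_scale`; at zero the classes
are statistically identical, which provides the null cohort used for
negative controls.

Default class effects (all configurable):

* **PVC burden** `pvc_prob`: log-normal, median 0.005 per beat for C0
  (non-VT) versus 0.05 for C1 — a ten-fold shift applied on the log scale.
  No quantitative PVC-burden contrast between VT and non-VT Holter
  populations is established in the literature we rely on; this is a stated
  working assumption chosen so that the default cohort is separable but not
  trivially so.
* **RR fragmentation** `frag_coeff`: the lag-1 autocorrelation of the RR
  increments, Normal(0.10, 0.15) for C0, shifted by −0.30 for C1.
* **Patient information** (age, sex, BMI, smoking) is drawn independently
  of class, deliberately: the PI-only model is the package's negative
  control and should score at chance on the default cohort.

The sinus RR series is built from an order-1 autoregressive process on the
RR *increments* with coefficient `frag_coeff`. A negative coefficient makes
successive increments anti-correlated, i.e. the series keeps turning — the
behaviour the fragmentation indices (PIP, IALS, PSS, PAS) quantify. Pure
integration of AR(1) increments is a random walk and drifts without bound,
so the integration leaks (coefficient 0.98 per beat) and the result is
rescaled to the profile's `rr_sd`; the leak is slow enough that the local
sign structure of the increments — what fragmentation measures — is
preserved. Sinusoidal modulations at 0.1 Hz (`lf_amp`) and 0.25 Hz
(`hf_amp`) supply the LF and HF spectral peaks. A PVC shortens its own
interval to `pvc_coupling` times the current RR and the following interval
is extended so the pair sums to twice the local mean RR — a full
compensatory pause, the textbook signature of ventricular ectopy, and what
makes PVCs detectable by prematurity rules downstream.

The waveform is a sum of five Gaussian bumps per beat (P, Q, R, S, T).
Normal beats span about 80 ms between the outer 3-sigma bounds of Q and S.
Ventricular beats are rendered with no P wave, QRS widths multiplied by
`pvc_width_factor` (default around 2, giving a wide complex well over the
120 ms criterion), an inverted, dominant S deflection and an inverted T —
the gross morphology change real PVCs show. The ventricular beat's
annotation is placed on its dominant rendered deflection, which is what any
R-peak detector locks onto. Additive noise comprises a 0.25 Hz baseline
wander, white noise at the profile's `noise_level`, a 50 Hz mains
sinusoid, and `n_bad_segments` episodes of 20-fold amplified white noise
that emulate poor-contact stretches. Leads are gain-scaled copies of one
source waveform with independent noise realisations; the analysis is
single-lead throughout, so multi-lead realism is out of scope.

VT runs can be injected (`inject_vt_runs()`) as stretches of consecutive
ventricular beats at a fixed rate above 100 b.p.m., replacing sinus beats
so total duration is conserved. Their sample intervals become the
`vt_events` that the window-exclusion stage must remove — the classifier is
never allowed to see VT itself.

**What the generator does not emulate**: atrial fibrillation and other
supraventricular arrhythmias, respiration beyond the sinusoidal HF
modulation, electrode motion artefacts with realistic spectra, pacemaker
spikes, and genuine 12-lead geometry. Consequently, a pipeline that passes
every test here has demonstrated *internal* correctness (each stage
recovers what the generator put in) — not clinical performance on real
Holter data, where the published discrimination is far from perfect.

## Windowing and signal quality

Recordings are band-pass filtered with a zero-phase second-order IIR
(0.67–100 Hz passband) plus a 50 Hz notch (quality factor 30; the source
specifies only the frequency). Zero phase is obtained by forward–backward
application, which doubles the effective attenuation; that is the stated
design. When the sampling rate leaves no room for the upper edge
(`fs < 200` Hz), the edge is clipped to `0.45 fs` with a warning; below
100 Hz of Nyquist headroom the notch is skipped.

Signals are split into consecutive, disjoint 30-minute windows from sample
zero; a trailing partial window is discarded so all windows are identically
sized (the alternative — keeping ragged tails — would make window features
incomparable). Window quality is the **bsqi**: two algorithmically
independent QRS detectors (a Pan–Tompkins-style energy detector and a
curve-length detector) run on each lead, and the window's score is the F1
of their one-to-one greedy matching within 150 ms, maximised over leads.
The matching sweep (advance the earlier unmatched detection, match when
within tolerance) attains the true maximum matching cardinality for points
on a line, and the tests assert equality with a brute-force dynamic
program. Windows with bsqi strictly above 0.8 are high quality; a window at
exactly 0.8 is excluded (the inclusion and exclusion rules meet at the
boundary; strict inclusion is the documented choice). Recordings with fewer
than six high-quality windows are dropped entirely. At desk scale the
six-window rule scales linearly with duration — six per 24 hours means one
per hour — and the desk-scale configurations set `min_good_windows`
accordingly.

One property of bsqi worth knowing: as noise grows the score does not fall
to zero but saturates near 0.6, because two refractory-limited detectors
firing pseudo-randomly still agree by chance within a 150 ms tolerance.
The gate at 0.8 sits well above this floor, so the rule works; but bsqi
differences *below* about 0.65 carry no information, and a short noise
burst inside an otherwise clean window can leave bsqi above the gate. The
beat classifier therefore additionally voids beats whose ±100 ms
neighbourhood contains no detectable isoelectric segment (label `none`),
which is what the 20-fold noise episodes produce.

## Beat analysis

Fiducial points are delineated per beat: QRS onset and offset by a
sustained slope-threshold search (first point, moving outward from R, where
the absolute derivative of a lightly smoothed copy stays below 5% of the
local peak slope for ~25 ms) within ±100 ms of R; the T end by the tangent
method; the P wave as the largest positive interior bump in the 200 ms
before QRS onset, never reaching into the previous beat's T wave (350 ms
after the previous R), and declared absent below the local noise floor.
The slope threshold is floored at 2.5 times the window-wide median absolute
slope — a noise estimate, since QRS complexes occupy a minority of samples
— and that floor is capped at 20% of the beat's own peak slope so that
low-amplitude beats in heavy noise degrade to wide edge-clamped bounds
rather than to spurious boundaries at slope dips.

Beats are classified into the standard five classes by deterministic rules
on three per-beat quantities: QRS duration, prematurity (previous RR over
the median of the eight preceding normal RRs), and correlation with a
running template of the dominant QRS morphology (exponentially weighted,
alpha = 0.05, initialised from the medoid of the first ten beats).
`V` = wide (>120 ms), premature (<0.90) and morphologically dissimilar
(correlation < 0.8); `S` = premature but narrow; `F` = wide with
intermediate correlation (0.8–0.95); `none` = no fiducials or invalid
local context; otherwise `N`. The published clustering-based classifier
this stands in for is used in the original analysis only to produce
five-class ratios per window; a deterministic rule set keeps the pipeline
self-contained and testable, and all four thresholds are arguments.

## Features

23 HRV features per window: time domain (AVNN, SDNN, RMSSD, pNN20, pNN50,
SEM), fragmentation (PIP, IALS, PSS, PAS), frequency domain (total, VLF,
LF, HF power, LF/HF, normalised LF and HF) and nonlinear (SD1, SD2,
SD1/SD2, sample entropy, DFA slopes). Conventions that matter:

* HRV is computed on **all** RR intervals in the physiological range
  300–2500 ms, including intervals around ectopic beats — the class signal
  partly *is* the PVC-induced irregularity, so an NN-only restriction would
  remove the effect being measured.
* A zero increment counts as a sign change in the fragmentation indices
  (one of two conventions; fixed and asserted by the closed-form tests:
  PIP of a perfect alternation with n intervals is (n−2)/n, PAS is 1, a
  monotone ramp gives PIP 0 and IALS 1/(n−1)).
* Spectral powers come from a Lomb–Scargle periodogram of the unevenly
  sampled intervals — no resampling, which would interpolate across
  compensatory pauses exactly where ectopy is high.
* SD1 is defined as RMSSD/√2 (asserted to 1e−9), SD2 from the SDNN
  identity; sample entropy uses m = 2, r = 0.2·SDNN (C++ kernel,
  Richman–Moorman counting); DFA slopes are fitted over boxes 4–11 and
  12–64 with a finite-size correction — each F(s) is normalised by its
  exact white-noise expectation (computable in closed form for linear
  detrending), without which the 4–11 box range is biased upward by ~0.12
  even for i.i.d. data.

22 morphological measures per beat (durations, amplitudes relative to the
isoelectric level, areas, slopes, QTc by Bazett and Fridericia), each
summarised over the window's classifiable beats by mean, median, minimum,
maximum and interquartile range (110 features), plus the five beat-class
ratios — 115 MOR features. Beats labelled `none` are excluded from the
waveform statistics but counted in `NoneRatio`. Four PI features (age,
sex, BMI, smoking) are broadcast per recording. Missing values are kept as
`NA` in the feature table; imputation is part of model training and is
fitted on training folds only.

## Classification and evaluation

The window classifier is a gradient-boosted tree ensemble (xgboost).
Hyperparameters — tree count, depth, learning rate, subsampling, minimum
child weight, a positive-class weight for the class imbalance, and the
mRMR energy threshold — are tuned by sequential model-based ("Bayesian")
search: a Latin-hypercube initial design, then a random-forest surrogate
with an upper-confidence-bound acquisition proposes each next
configuration; 50 evaluations by default. With a fixed seed the entire
search is deterministic. Each configuration is scored by 4-fold inner
cross-validation with folds partitioned **by patient** ("stratified by
patients" read as patient-disjoint — the reading consistent with the
no-leakage requirement), on the patient-level AUROC after median
aggregation; an inner fold that ends up single-class scores 0.5 with a
warning.

mRMR ranks features greedily by mutual information with the label (on
10-bin quantile-discretised values) minus mean mutual information with the
already-selected set; the selected set is the smallest prefix whose
cumulative relevance reaches the energy fraction, and the energy is itself
a tuned hyperparameter. The ranking does not depend on the energy, so each
fold ranks once and every candidate configuration cuts a prefix.

The outer loop draws 10 independent patient-level train/test splits (10 C1
and 130 C0 test patients at full scale, scaled to ⌈0.2 × class⌉ for
smaller cohorts); all recordings of a patient stay on one side. The
reported metric is the mean ± sample SD of the patient-level AUROC over
the outer repeats. Feature screening uses the two-sided Mann–Whitney test
on per-recording feature values (the median over that recording's retained
windows — recording-level observations respect independence; the mean is
available as an option), exact when both groups have at most eight
observations without ties, with no multiple-testing correction by default
(a flat P < 0.05 criterion; Benjamini–Hochberg is available). ROC curves
are pooled across repeats by vertical averaging on a 101-point FPR grid
with median and interquartile envelope.

## Problem sizes and numerical choices

The package's test and acceptance runs use desk-scale cohorts: 40 C1 / 160
C0 patients with one-hour recordings at 128 Hz for the end-to-end
discrimination checks (the windowing and counting rules scale linearly
with duration), a 100-patient subset for the PVC-recovery regression, 12 +
12-patient cohorts over 20 seeds for the screening-recovery check (the
smallest per-class n at which the exact Mann–Whitney test has ~98% power
for the PIP effect under the default class-conditional parameters), and
reduced search budgets (10 configurations, 3 outer repeats) for the tuned
models. Full-scale settings (24-hour recordings, 50 search iterations, 10
repeats) are the defaults of the exported functions.

Other fixed numerical choices: sample indices are 0-based with half-open
window intervals; the bsqi matching tolerance defaults to 150 ms (the
conventional inter-detector agreement window; configurable); the detectors
enforce a 250 ms refractory period; IQR uses Q3 − Q1 with midpoint
interpolation; pNNx uses strict inequality; ties in the greedy matching
resolve toward the earlier detection. Degenerate inputs are mapped to
explicit missing values rather than zeros: short windows, constant RR
series (SampEn undefined at r = 0), and recordings shorter than one window
all propagate `NA`s with warnings.

## Known limitations

The beat classifier is a rule-based stand-in with fixed thresholds; on real
data with bundle-branch blocks or aberrant conduction its fusion and
supraventricular classes would be unreliable. The bsqi floor means short
noise bursts inside a window are handled by the beat-level context rule,
not the window gate. The generator's PI features are class-independent by
design, so nothing here validates the use of clinical covariates. And all
performance numbers produced by the tests and the acceptance script are
properties of the synthetic cohort — they demonstrate that the pipeline
recovers planted structure, not that it attains any particular accuracy on
hospital Holter data.
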