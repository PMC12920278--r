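---
title: "Screening obstructive sleep apnea from pulse oximetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening obstructive sleep apnea from pulse oximetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed from the apnea–hypopnea index
(AHI): the number of apnea and hypopnea events per hour of sleep, scored from
full polysomnography. Pulse oximeters are the most accessible home-screening
sensor, but screening on oxygen saturation (SpO2) alone misses hypopneas that
end in a cortical arousal without a meaningful desaturation. The same sensor,
however, records a raw photoplethysmogram (PPG), and two derived series carry
arousal information:

* **PWA** (pulse wave amplitude) — the peak-to-trough amplitude of each pulse.
  Arousals trigger sympathetic peripheral vasoconstriction, seen as transient
  PWA drops.
* **PPI** (pulse-to-pulse interval) — the time between successive systolic
  peaks, a surrogate for the RR interval. Arousals shorten PPI the way they
  accelerate heart rate, and PPI variability can be analysed with the usual
  heart-rate-variability (HRV) toolbox.

`oxipulse` implements the full analysis: raw PPG + SpO2 → beat series → 60-s
segments → 37 features → SVM classifiers under subject-grouped nested
cross-validation → per-subject AHI estimates and AHI ≥ 15 screening. Because
no public dataset accompanies the design, the package ships a synthetic
polysomnography generator with known ground truth for every stage, and the
whole test suite runs against it.

## Pipeline

### Preprocessing

PPG is resampled to 128 Hz (windowed-sinc polyphase filter), band-passed
0.7–20 Hz with a zero-phase order-4 Butterworth (forward–backward, so peak
times are not shifted; edges are reflection-padded to suppress transients).
Artifact rejection works on non-overlapping 60-s windows: samples deviating
from the window mean by more than 1.5 window standard deviations are flagged,
and any beat whose peak or trough lands on a flagged sample is dropped. A
zero-variance window flags nothing. Systolic peaks are local maxima at least
`60/180` s apart whose height exceeds 30% of the rolling (10-s) signal
amplitude — the adaptive threshold lets the detector follow arousal-related
amplitude drops. Each peak's time is refined to the centroid of its crest
(samples within 90% of peak height): on rounded pulse crests the raw argmax
wanders under noise, which would masquerade as pulse-rate variability. Beats
are cleaned to "NN" (normal-to-normal) status: PPI outside 0.33–2.0 s, or
jumping more than 30% from the median of the five preceding valid intervals,
is masked. PPI and PWA are then cubic-spline interpolated onto a uniform 4 Hz
grid for spectral analysis. SpO2 (16 Hz) is used at its native resolution.

### Segmentation and labeling

Recordings are tiled into non-overlapping 60-s windows (trailing partial
window discarded). A window is positive when apnea/hypopnea annotations
occupy at least 10 s of it. Overlap is summed across events by default
(clustered short events are one physiological burden); `mode = "single"`
gives the literal one-event reading. Windows are half-open, so an event
touching the right edge contributes nothing. A window is arousal-tagged when
any arousal annotation intersects it by more than 0 s.

### Features (37 per segment)

* **PPI time domain (13)** — Mean_NN, Max_PR/Min_PR (bpm), SDNN, CVNNI, SDSD,
  CVSD (RMSSD over mean NN), NN50/pNN50, NN20/pNN20, RMSSD, Range_NN.
* **PPI nonlinear (3)** — sample, fuzzy and dispersion entropy of the 4 Hz
  PPI series.
* **PPI frequency domain (7)** — VLF (0.003–0.04 Hz), LF (0.04–0.15 Hz),
  HF (0.15–0.4 Hz) Welch band powers, LFnu, HFnu, LF/HF, spectral entropy.
* **PWA (7)** — Max, Min, SD, CV of beat-wise PWA, plus VLF/LF/HF of the
  4 Hz PWA series (pulse-amplitude variability).
* **SpO2 (7)** — Min, Mean, SD, Variance, plus the three entropies.

Numerical choices the catalogue leaves open, and how this package fixes them:

* Entropy parameters: `m = 2`, tolerance `r = 0.2 × series SD`, delay 1,
  fuzzy membership exponent 2, dispersion classes `c = 6` with the normalised
  variant — the standard HRV-entropy settings. Constant series are defined to
  have zero entropy; an undefined SampEn (no template matches) returns `NA`
  and flags the segment.
* Welch PSD: 120-sample Hann sub-windows, 50% overlap, linear detrend — three
  averages per 240-sample segment. Band powers integrate the PSD
  trapezoidally with values interpolated at the band edges. A 60-s window
  cannot resolve the VLF band (1/60 Hz > 0.003 Hz); VLF is integrated over
  the nominal band anyway and is resolution-limited by construction.
* SpO2 entropies are computed on a 1 Hz mean-decimated trace: at 16 Hz the
  oximeter output is heavily oversampled relative to desaturation dynamics
  and template matching saturates on redundant samples.
* Max_PR/Min_PR use cleaned NN intervals, not raw PPI.

PWA is an amplitude in arbitrary, sensor-dependent units, so PWA features are
min–max normalised within each subject; the same scaling is applied to the
PPI family by default (`scope = "pwa_ppi"`, with `"pwa_only"` available).
SpO2 features stay on their physical % scale. Constant columns map to 0; a
subject with a single segment is an error, since the range is undefined.

### Modeling and evaluation

Cross-validation is grouped by subject: all of a subject's segments share a
fold, so no subject contributes to both training and testing. Within each
training fold, in order: recursive feature elimination (one feature per step,
ranked by random-forest impurity importance) scored by subject-grouped inner
5-fold AUC, choosing the smallest subset within one standard error of the
best; random undersampling of the majority class to exact balance; z-scoring
fitted on training rows; and an exhaustive search of the four-point SVM grid
(cost {0.1, 1} × kernel {RBF, polynomial degree 3}) by inner-CV AUC. The
search space is so small that randomized and exhaustive search coincide; the
exhaustive version is deterministic. The fitted SVM exposes a continuous
decision score (oriented so larger means more apneic) and a binary prediction
at score 0.

Per-segment performance is accuracy, sensitivity, specificity, precision and
AUC per fold, aggregated as mean ± SD. Detection is also stratified by the
arousal tag within true-positive segments. Per subject, the estimated AHI is
the count of positive segments divided by recording time in hours — each
positive minute counts as one event, and recording time (not sleep time) is
the denominator, a known source of underestimation. Screening calls a subject
positive when estimated AHI ≥ 15; severity bins are `<5` none, `5–<15` mild,
`15–30` moderate, `>30` severe. Pearson correlation between estimated and
reference AHI is computed on the raw scale.

## The synthetic generator

`generate_recording()` plants ground truth for every downstream stage:

* Beats are scheduled iteratively; PPI carries 0.25 Hz respiratory
  modulation (±2%), 1% beat-to-beat noise, and the arousal response. PWA
  carries a slow 0.1 Hz vasomotor oscillation (±5%) and 4% log-normal
  beat-to-beat noise.
* Events are evenly spaced with ±10% jittered gaps so the scheduled count —
  hence the reference AHI — is exact. Durations are uniform on 12–28 s
  (AASM events must last ≥ 10 s). Every event ends in an 8-s arousal
  beginning 2 s before event end. During the arousal window PWA is multiplied
  by `1 − pwa_drop_frac` (default 0.4) and PPI by `1 − ppi_shortening_frac`
  (default 0.15), both recovering exponentially with a 15-s time constant —
  the delayed autonomic response that motivates 60-s windows. The
  quantitative size of the PPI shortening is a free parameter of the
  generator, not a literature claim.
* SpO2 rests at 97% with slow red-noise wander (SD 0.3%, so negative-segment
  SpO2 variance is informative but not degenerate). Apneas and the
  desaturating 70% of hypopneas are followed by a Gaussian-shaped dip of
  `desat_depth_pct` (default 4 points; apneas 30% deeper and wider) with its
  nadir 15 s after event end. The remaining hypopneas are arousal-only: full
  PWA/PPI response, no dip — the phenotype PWA/PPI features are meant to
  rescue.
* The PPG waveform is synthesised by phase: each cycle is an asymmetric
  soft-clipped cosine (fast systolic rise peaking at 20% of the cycle, slow
  decay, small dicrotic bump) whose peak-to-trough amplitude equals the
  planted PWA. The soft clipping keeps the crest factor near 1.27, matching
  band-passed finger PPG; a spikier wavelet would put every systolic crest
  beyond the 1.5-SD artifact threshold and the artifact rule would censor the
  signal itself rather than outliers. Additive white noise (SD 0.02 amplitude
  units) and a 2-s moving-average subtraction (AC component only) finish the
  trace.

`generate_cohort()` allocates subjects to the four severity bins by
largest-remainder rounding (the default mix 12.2/24.4/35.6/27.8% reproduces
the clinical cohort composition the design targets), draws each subject's
AHI uniformly within its bin, varies resting pulse rate across subjects
(55–75 bpm), and flags half the cohort with a comorbidity for stratified
screening reports.

What the generator deliberately does **not** emulate: sleep stages and wake
time (so the synthetic positive-segment fraction, ~34% at the default mix, is
higher than the ~22% seen in overnight hospital recordings whose denominator
includes wake), sensor-contact drift, motion artifacts, mixed/central apneas,
and within-subject PPG-magnitude nonstationarity. Passing tests therefore
demonstrate that the pipeline recovers planted physiology of realistic shape
and size — not that hospital-data performance numbers transfer.

## Reproducibility and problem sizes

Every stage derives its seed from one run seed, so a run's configuration
plus seed reproduces its outputs byte-identically; stages can be re-run in
isolation. The study-scale demonstrations use 12 subjects × 2 h (1440
segments) — large enough for ~500 positive segments and stable fold metrics,
small enough to run on a laptop core. Random forests use 100 trees,
single-threaded, seeded. The null-cohort control (all event-locked responses
disabled) checks that the pipeline finds nothing when there is nothing to
find: held-out AUC stays near 0.5 because grouped folds, fold-local feature
selection and fold-local tuning leave no leakage path.

## Known limitations

* A 60-s positive segment counts as exactly one event in the AHI estimate;
  long events split across windows and clustered events in one window bias
  the estimate in opposite directions (the oracle-classifier recovery check
  bounds this at ±20% for the default event geometry).
* VLF power on 60-s segments is resolution-limited (see above); it is kept
  for catalogue fidelity, and its within-subject normalisation preserves its
  rank information.
* The comparison utility for per-fold metrics (repeated-measures ANOVA +
  Bonferroni paired t-tests) treats folds as the repeated unit, as is
  conventional, but five folds give little power; it is a reporting tool,
  not an inferential claim.
* Entropy features on 60-sample decimated SpO2 traces sit at the short end
  of recommended series lengths for `m = 2`; they are retained because the
  catalogue includes them and the brute-force oracles confirm the arithmetic,
  but their sampling variance is large.
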