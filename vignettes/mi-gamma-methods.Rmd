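---
title: "Linking resting gamma power to motor-imagery BCI performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking resting gamma power to motor-imagery BCI performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migamma)
```

## The scientific question

A sizeable fraction of motor-imagery (MI) brain-computer-interface users
cannot produce classifiable sensorimotor rhythm modulations ("BCI
illiteracy"). One candidate trait marker is the spatial profile of
resting-state gamma-band (30-70 Hz) activity: subjects whose resting gamma
concentrates over the prefrontal midline tend to reach higher MI
classification accuracy, whereas relatively high posterior gamma goes with
lower accuracy. `migamma` implements the complete analysis chain needed to
ask that question of a cohort — an MI performance estimator, a normalized
resting band-power statistic, and correlation maps with multiple-comparison
control — together with a synthetic M/EEG cohort generator that embeds a
known ground-truth coupling, so every stage of the chain can be validated
end to end.

## The performance estimator

Trials follow the standard two-class (left/right hand) MI design: 2 s of
fixation, a 3 s imagery phase triggered by a directional cue, 2 s of blank
rest and a uniform 0-2 s inter-trial interval; three runs of 40 trials give
120 trials per session. The recording is bandpass filtered to 8-30 Hz (the
mu and beta range carrying the event-related desynchronization, ERD), and a
2 s analysis window slides in 100 ms steps across the imagery phase — eleven
windows with starts 0.0-1.0 s.

Within one window, accuracy is estimated by grouped exhaustive-partition
cross-validation: trials are split into 10 equal, class-balanced groups, and
every one of the `choose(10, 7) = 120` ways of taking 7 training and 3 test
groups is evaluated. Per partition, common spatial patterns (CSP) are fitted
on the training trials only. CSP solves the generalized eigenproblem

    C1 w = lambda (C1 + C2) w

on the trace-normalized average class covariances; eigenvalues near 0 or 1
mark the most discriminative spatial filters, and the 5 filters from each
end of the spectrum (10 total) are kept. Each trial is projected through the
filters and the per-filter variance is the feature vector. A Fisher linear
discriminant (weights proportional to `Sw^-1 (m1 - m2)`, boundary at the
midpoint of the projected class means) is trained on the training features
and scored on the held-out trials. The window's accuracy is the mean of the
120 partition hit rates, and the maximum over window starts (earliest start
on ties) is the subject's MI accuracy. Refitting CSP inside every partition
is enforced — fitting it once on all trials would leak test information into
the spatial filters and inflate accuracy.

Choices the design leaves open, fixed here:

* group assignment is class-stratified and drawn once per session (not per
  window), so the accuracy curve is comparable across window starts;
* features are plain variances; a log-variance option exists but is off by
  default;
* the composite covariance is inverted by whitening (eigendecomposition of
  `C1 + C2`, then rotation), which is numerically stabler than a direct
  generalized eigensolve and mathematically identical;
* the FLDA scatter gets a ridge of `1e-8 * trace/dim` only when its
  condition number exceeds `1e10`.

## The resting-state statistic (RPL)

Resting recordings (60 s, eyes open) are bandpass filtered 1-100 Hz and
their power spectral density is estimated by Welch's method (2 s Hamming
segments, 50% overlap, mean-detrended). Band powers for theta (4-8 Hz),
alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-70 Hz) are trapezoidal
integrals of the PSD with linear interpolation at the band edges, so the
four bands tile the 4-70 Hz total exactly. The relative power level is a
two-step normalization:

1. `rel(ch, band) = power(ch, band) / power(ch, 4-70 Hz)` — each channel's
   band fraction (the four fractions sum to 1 per channel);
2. `RPL(ch, band) = rel(ch, band) / sum_ch' rel(ch', band)` — each band's
   channel profile is normalized to sum to 1.

Step 2 makes profiles comparable across subjects and puts all bands on a
common scale, which is what allows fixed-scale topographic comparison and
cross-subject correlation without channel or band bias. The defining
sentence of this statistic is ambiguous about the order of the two
normalizations; the order above is adopted because the reverse (normalizing
raw power across channels first) would make the statistic depend on overall
amplitude differences between channels, defeating its purpose.

## Correlation analyses

Subjects' best-window accuracies are correlated with their resting RPL in
two geometries:

* **five anterior-posterior regions** — channels within 0.35 of the midline
  are split at `y`-quantiles into prefrontal, frontal, central, parietal and
  occipital bands; each subject's band RPL is averaged per region and
  Pearson-correlated with accuracy (two-sided Student t test on
  `t = r sqrt((n-2)/(1-r^2))`), with a least-squares line of accuracy on
  RPL;
* **channel-wise maps** — the same test per channel and per band, with a
  Benjamini-Hochberg false-discovery-rate mask at `q = 0.1` over all
  channels.

Two-sided tests are used throughout. The BH (independence/PRDS) form is
used for FDR; the midline width 0.35 and the quantile split are
configurable because no published channel membership exists for the five
regions.

## What the synthetic cohort emulates

No public recordings accompany the analysis this package operationalizes,
so the generator is a first-class module with ground truth:

* **background**: per-channel independent noise with a 1/f amplitude
  spectrum (flattened below 1 Hz), scaled by `noise_scale`;
* **rhythms**: four shared band-limited noise sources (theta, alpha, beta,
  gamma; FFT-masked white noise with 1 Hz half-cosine edges), each
  multiplied by a slow log-normal amplitude envelope (cutoff 0.1 Hz, log-sd
  0.5) so band power waxes and wanes over seconds the way real rhythms do —
  this is what gives single-trial variance features a realistic spread and
  keeps cross-validated accuracies off the ceiling;
* **topography**: each band projects through Gaussian spatial gains —
  theta fronto-midline, alpha occipital, beta over both sensorimotor zones,
  gamma prefrontal plus a weaker occipital component;
* **ERD**: during the 3 s imagery phase, the 8-30 Hz component of the
  contralateral sensorimotor channels (disks of radius 0.25 around
  (±0.5, 0)) is multiplicatively attenuated so its variance drops by
  `erd_depth`, with 200 ms raised-cosine ramps at the phase edges. The
  component is extracted by zero-phase bandpass of the total signal, so the
  measured 8-30 Hz variance ratio between imagery and preparation equals
  `1 - erd_depth` up to sampling error;
* **cohort coupling**: `erd_depth` is drawn per subject from U(0.1, 0.7)
  and the prefrontal gamma amplitude follows
  `0.5 + 1.0 * erd_depth + N(0, 0.1)`; the occipital gamma amplitude uses
  slope `-0.6`. Since accuracy is monotone in ERD depth, this embeds the
  anterior-positive / posterior-negative correlation gradient the analysis
  should recover, with a recoverable sign by construction.

Defaults were chosen once as representative study conditions: 500 Hz
sampling (acquisition systems in this literature run at 500-1000 Hz), a
152-channel MEG-like grid layout over the unit disk plus a 19-channel 10-20
EEG layout, 60 s rest, 3 runs x 40 trials. With `erd_depth = 0` the two
classes are generated identically (labels are assigned after the signal is
synthesized and modulate nothing), which grounds the chance-level null
check.

What the generator does **not** emulate: realistic forward-model field
spread (gains are Gaussian in sensor space), head movement, eye/muscle
artifacts, inter-channel noise correlation, or non-stationarities beyond
the slow amplitude envelope. Passing tests on this cohort therefore
validate the *pipeline* — its estimators, its cross-validation hygiene, its
statistics — not the neurophysiological claim itself, which requires real
recordings.

## Numerical choices and degenerate inputs

* Zero-phase filtering is a 4th-order Butterworth applied forward-backward;
  band edges must satisfy `0 < low < high < rate/2`.
* Epoch windows are half-open `[t_start, t_end)` with 0-based onset
  samples, so a 2 s window at 500 Hz is exactly 1000 samples.
* Welch PSD is one-sided density; a flat spectrum integrates to the
  bandwidth ratio (gamma/total = 40/66) exactly because band edges land on
  the 0.5 Hz grid of 2 s segments.
* CSP rejects a singular composite covariance with advice to reduce the
  channel count (whole-array CSP is known to overfit); eigenvalue ties are
  broken by eigenvalue index.
* FLDA breaks boundary ties toward the positive class of its `class_map`.
* `compute_rpl` rejects channels with zero 4-70 Hz power by name;
  `pearson_with_test` rejects constant inputs rather than returning NA.
* Recordings serialize to 16-bit EDF; the writer scales with the physical
  bounds exactly as stored in the 8-character header fields, bounding the
  round-trip error by one quantization step.

## Problem sizes used in the shipped checks

The package's own validation runs at reduced but stated scales, chosen as
the smallest sizes at which each property is meaningful: the null
chance-level check uses 20 sessions of the full 120-trial design at 30
channels and 500 Hz with the complete 10-group / 120-partition CV at one
window; the cohort sign-recovery check uses 3 cohorts of 20 subjects at 24
channels and 250 Hz with a 0.5 s window step. Sampling rate, channel count
and step size only trade statistical resolution against compute here; none
of the tested properties depends on them.

## Known limitations

* The RPL normalization order is a declared convention (see above), not a
  validated reconstruction of any particular prior implementation.
* Region membership and the midline width are configurable conventions for
  the same reason.
* The generator's shared-source band model makes spatial structure low-rank
  within each band; CSP on such data is easier than on real recordings, so
  absolute synthetic accuracies should not be read as expected real-data
  accuracies — only their ordering and the null level carry meaning.
* Only two-class (left/right) designs are supported; multi-class CSP
  extensions and shrinkage covariance estimators are out of scope.

## A minimal session

```{r example, eval = FALSE}
lay <- meg_grid_layout(30)
p   <- subject_params(erd_depth = 0.4, seed = 7)

ses <- generate_mi_session(lay, p)
acc <- sliding_accuracy(ses$recording, ses$events, seed = 1)
acc$best_acc

rest <- generate_resting(lay, p)
rpl  <- resting_rpl(rest)

report <- run_study(study_config(
  cohort = cohort_config(n_subjects = 10, layout = lay)))
report$region$gamma
```
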