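---
title: "Detecting speech-production intent in intracranial recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting speech-production intent in intracranial recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentdecode)
```

## The question and the approach

Temporal and parietal cortices are heavily involved in *perceiving* speech.
Before signals from these areas can drive a speech brain-machine interface,
one has to show that they carry information about the *intent to produce*
speech — and that this information is present strictly **before** the voice
starts, so it cannot be auditory self-monitoring. `intentdecode` implements
the full analysis chain for that question on ECoG/sEEG recordings of cued
word-production tasks:

1. **Signal conditioning.** Zero-phase IIR notches at 60/120/180 Hz, common
   average referencing over clean channels, and high-gamma (70–200 Hz) power
   via a *causal* linear-phase FIR filter, Hilbert-transform analytic
   amplitude, squaring, and exact group-delay correction.
2. **Causal feature windows.** Mean high-gamma power in 100 ms
   non-overlapping windows whose end is swept relative to voice onset;
   contrast windows (resting silence, or the middle of an instructed delay)
   are fixed and never offset.
3. **Decoding.** RBF-kernel SVMs with nested cross-validation (stratified
   80/20 outer resampling, 5-fold inner grid search), an empirical chance
   distribution from label shuffles, add-one permutation p-values,
   Benjamini–Hochberg FDR across offsets or electrodes, and the earliest
   significant offset as the latency estimate.
4. **State-space view.** Demixed PCA separating condition (intent vs
   silence) from shared temporal dynamics.
5. **Spatial view.** k-means clustering of voice-onset-locked envelope time
   courses into production-like, perception-like and unmodulated electrode
   groups, plus per-electrode decoders.

Because no public recordings accompany this problem, the package ships a
first-class synthetic-recording generator ([`sim_config()`],
[`generate_recording()`]) that plants known intent signals, and every stage
is validated against that ground truth.

## The filter-delay arithmetic

The high-gamma chain must be causal (a BMI cannot look into the future), so
the band-pass is a one-way linear-phase FIR filter. Its tap count follows
$N \approx 4 f_s/\Delta f$ with transition bandwidth $\Delta f = 10$ Hz,
rounded to the nearest integer, and its constant group delay is
$\tau = (N-1)/(2 f_s)$: 199 ms, 199.5 ms and 199.75 ms at 500, 1000 and
2000 Hz. `band_power()` shifts the squared analytic amplitude backward by
exactly $\tau$ and masks the trailing $\tau$ (and the startup transient) as
invalid; the mask propagates through epoching and feature extraction, so no
feature window ever touches filter edge artifacts. The FIR design is a
Hamming-windowed sinc (`signal::fir1`), consistent with the tap-count rule.

## What the generator emulates — and what it does not

Each synthetic channel is the sum of unit-RMS 1/f (pink) Gaussian noise,
line-noise sinusoids at 60/120/180 Hz, a shared common-mode pink trace, and,
for channels with a *production* or *perception* role, a band-limited
70–200 Hz carrier multiplied by a raised-cosine envelope. The envelope rises
over 100 ms starting at `voice_onset - production_lead` (default 300 ms,
matching pre-vocal high-gamma ramps) or `voice_onset + perception_lag`
(default 100 ms, auditory self-monitoring) and is sustained through the
word. `modulation_snr` is the ratio of planted plateau amplitude to the
background's high-gamma RMS; 0 plants nothing and is the null condition.

Trial timing follows the delayed-reading design: stimulus 1.5 s, instructed
delay 1.5 s (long enough to contain the 0.9–1 s mid-delay control window),
go cue, a uniform 0.3–0.8 s reaction time (jittered per trial so
voice-locking is distinguishable from cue-locking), 0.6 s word, and a 2.5 s
inter-trial interval (1.2 s for auditory tasks, whose silence windows start
0.5 s instead of 1.5 s after voice offset). The configuration validator
refuses timings whose silence windows would overlap the next trial.
Not emulated: cortical geometry, volume conduction, spikes, movement or
electrode artifacts, behavioural errors. Passing tests therefore demonstrate
correctness of the *analysis machinery* under the stated noise model, not
robustness to every pathology of clinical recordings.

One desk-scale artifact deserves emphasis: with only 8 synthetic channels,
common average referencing feeds 1/8 of the planted production modulation
into every other channel. That crosstalk is real (and negligible at
clinical channel counts); tests that assert per-channel role recovery
(clustering, per-electrode decoding, dPCA separation) therefore use
fixtures without common-mode noise and skip CAR, while the decoding sweep
keeps the full chain.

## The empirical null: two choices that matter

Two deliberate choices depart from the most literal reading of the
procedure, both made after pilot simulations exposed calibration defects.

**Shuffles are coherent across outer iterations.** The outer loop resamples
80/20 splits, so different iterations share test rows and their accuracies
are positively correlated. Shuffling each iteration's test labels
independently builds a null for the across-iteration mean that ignores this
correlation: on pure-noise data its p-values were anti-conservative
(about twice the nominal tail mass at 0.05). Each shuffle therefore permutes
the trial labels once at the dataset level, and every iteration is re-scored
against the permuted labels of its own test rows, which reproduces the
correlation structure of the observed statistic. With a single outer
iteration (where no such correlation exists) and a small test set, the null
is enumerated exhaustively over test-set label arrangements and the p-value
is exact.

**The percentile gate uses the pooled single-iteration chance
distribution.** A result is significant only if (a) its BH-adjusted add-one
permutation p-value is below $\alpha = 0.05$ *and* (b) the observed mean
accuracy exceeds the 95th percentile of the pooled distribution of
single-iteration shuffled accuracies. The pooled distribution is wider than
the distribution of shuffle means; gating on it is deliberately strict.
Without it, a sweep containing ten genuinely decodable offsets relaxes the
step-up threshold to roughly $11\alpha/23 \approx 0.024$, and a chance
offset clears that bar in a fifth of sweeps — the earliest-significant
-offset latency estimate would then be dominated by false alarms even with
perfectly calibrated p-values. With the gate, the test
suite's recovery experiment places the first significant offset within one
window of the planted 300 ms lead in at least 90% of its 20 seeded repeats,
and the false-positive rate on null data stays within the binomial envelope
of the nominal 5%.

## dPCA: marginalizations, regularization, variance accounting

Trial-averaged, Savitzky–Golay-smoothed (4th order, 201 ms) condition means
for intent (500 ms pre-voice-onset) and silence (1–1.5 s post-voice-offset)
are mean-centred and split into a condition-independent marginalization
(the across-condition mean time course, tiled) and its residual (the
condition contrast). For each marginalization a ridge-regularised
reduced-rank regression of the marginalized data on the full data yields
paired decoder/encoder axes.

The ridge default is $10^{-2}$ of total variance. Near-unregularised fits
invert an ill-conditioned channel covariance and assign decoder weights
tens of times larger to *unmodulated* channels than to the channels
carrying the condition pattern — amplified chance structure. At $10^{-2}$
the decoders align with their encoders and the reconstruction $R^2$ cost is
under 1%. Per-component explained-variance fractions are
$s_i^2/\lVert X\rVert^2$; because components from different marginalizations
are not mutually orthogonal these fractions need not sum to the
reconstruction $R^2$, which is reported separately (`total_explained`) and
reaches 1 at vanishing regularization on full-rank data. Single-trial
projections ([`dpca_project()`]) apply the fit's smoothing before
projecting, so they live on the same signal scale as the fit.

## Clustering: operation order and onset labelling

Envelopes are z-scored per electrode at the *single-trial* level
(`epoch(..., z_score = TRUE)`), averaged across trials, then smoothed with
a 25 ms-SD Gaussian. The order matters: re-normalising after averaging
would blow unmodulated electrodes' residual noise back up to unit variance
and destroy the archetype structure the clustering is meant to find (role
recovery on the reference fixture drops from ARI 1.0 to 0.46). k-means runs
with 20 restarts for each k in 2–10; the cluster count is chosen at the
elbow, formalised as the largest positive second difference of the mean
within-cluster distance curve.

Cluster labels come from centroid onsets: the first time a centroid exceeds
its baseline (first 250 ms) mean + 2 SD and stays above for at least 50 ms.
Onsets are measured on *unsmoothed* trial-averaged centroids: the 25 ms
Gaussian kernel smears rising edges roughly 50 ms backward, which is enough
to push a perception cluster rising 100 ms after voice onset across the
t = 0 boundary and mislabel it as production. Onset < 0 labels production,
onset ≥ 0 perception, no sustained crossing unmodulated. On the reference
fixture the recovered onsets are −0.28 s and +0.11 s for planted leads of
−0.30 s and +0.10 s.

## Numerical conventions and degenerate inputs

* Time is seconds from record start; sample index of time $t$ is
  $\lfloor t f_s \rfloor + 1$ (1-based, epsilon-guarded); feature windows
  are half-open $[a, b)$; epochs include both endpoints, so a
  $[-1, 0.5]$ s window at 500 Hz holds 751 samples.
* Class balancing subsamples the majority class without replacement under a
  seed derived from the configuration seed; one generator seed fans out
  deterministically into per-channel, per-trial and per-stage substreams.
* Grid-search ties resolve to the smallest penalty, then the smallest
  kernel width; zero-variance feature columns are left unscaled rather than
  divided by zero; a zero-SD channel z-scores to zeros with a warning.
* Trials whose windows touch masked samples are dropped and reported, never
  imputed; offsets whose classes empty out are marked missing in the sweep,
  never fabricated.
* All-identical electrodes collapse to a duplicate-centroid two-cluster
  solution flagged `degenerate`; rank-deficient dPCA input without
  regularization produces an error advising a nonzero ridge.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
leaving comfortable statistical margins: the latency-recovery experiment
uses 20 seeded repeats of 8 channels × 150 trials at 500 Hz with 10 outer
iterations, a 2-point hyperparameter grid and 200 shuffles per offset; the
false-positive audit uses 200 null datasets of 4 channels × 20 trials with
3 offsets and 100 shuffles each; fixtures for role recovery use 8 channels
× 40 trials. The iteration count and grid size only trade statistical
precision for time; the full-scale settings (20 iterations, 4 × 5 grid,
500 shuffles) remain the package defaults.

## Known limitations

* Per-electrode adaptive high-gamma sub-bands are not implemented; a fixed
  70–200 Hz band is used for all channels.
* The instructed-delay control requires a task with a delay of at least
  1 s; no-delay task variants support only the silence contrast.
* The generalized-cross-validation selection of the dPCA ridge is not
  implemented; the fixed default has proven adequate on well- and
  ill-conditioned synthetic inputs.
* EDF import/export is not provided; signals travel in a flat
  binary + JSON container and events in a BIDS-style TSV.
* The permutation machinery conditions on fitted predictions; a full
  refit-per-shuffle null would also capture hyperparameter-selection
  variability, at two orders of magnitude more compute.
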