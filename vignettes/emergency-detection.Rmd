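---
title: "Detecting operator emergencies from EEG: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting operator emergencies from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emergeeg)
```

## The problem

An operator steering a drone through a cluttered space produces a
stereotyped neural response when an emergency (imminent collision) appears
on screen: an early occipito-parietal negativity around 0.2 s resembling the
visual mismatch negativity (vMMN), a centro-parietal positivity, and a
frontal slow negativity around 0.6 s resembling the contingent negative
variation (CNV).  `emergeeg` implements the full workflow for studying and
exploiting that response: a synthetic session generator, a causal
preprocessing chain, a hierarchical discriminant (HDCA) decoder, ERP peak
statistics, and a simulated online detection protocol scored by recall,
false alarm rate (FAR), accuracy and response time.

The package is self-contained: no recorded EEG ships with it.  The
generator plays the role of the experiment, which makes every downstream
stage testable against known ground truth.

## The experimental paradigm

A session is `n_runs = 20` runs of `trials_per_run = 12` trials; each trial
is one non-emergency video (default 6 s, configurable — the source paradigm
does not fix it; it must exceed 3 s so the pre-onset "normal" training
window predates the event) followed immediately by one 5-s emergency video.
Both video onsets are events; a full session therefore has 240 emergency
and 240 non-emergency events.  Recordings are 37 scalp channels plus two
EOG channels at 1000 Hz.  Onsets are 0-based sample indices; the event
onset is the first stimulus sample.

```{r}
cfg <- paradigm_config()
sch <- build_schedule(cfg)
sch
```

## The synthetic subject

### ERP templates

Each condition's response is a sum of Gaussian-envelope components
(`erp_component`): peak amplitude (uV), peak latency (s), width (Gaussian
SD, s), and per-channel gains in [0, 1].  The default amplitudes and peak
latencies are the grand-average values the generator is asked to reproduce:
emergency POz negativity -0.43 uV at 0.2 s, positivity +0.84 uV (+0.72 uV
non-emergency), Fz negativity -1.61 uV at 0.6 s (-0.70 uV non-emergency).
The envelope shape, the widths, the positivity latencies (0.55 s emergency,
0.45 s non-emergency: the preceding negativity delays it) and the spatial
gain profiles are modelling choices; only the peak values above are
anchored.  The non-emergency response carries no posterior negativity — the
mismatch component is specific to emergencies — which is what makes the two
conditions separable at all in the early post-onset window.

### Background noise

`noise_spec(background_sd = 10)` fixes the total per-channel background RMS
at 10 uV, composed of three parts:

* a spatially coherent alpha-band rhythm (8–12 Hz, three smooth spatial
  patterns; 98 % of the variance),
* a spatially coherent 1/f slow component (0.1 %),
* channel-independent broadband white noise (the rest, about 2 uV RMS).

This composition is deliberate and is the single most consequential design
decision in the package, so it deserves an honest paragraph.  The decoder
operates in the 0.1–5 Hz band, where the component amplitudes are at most
1.6 uV.  Any background variance placed in that band competes directly with
the signal; variance placed in the alpha band is removed by the band-pass
and costs nothing.  The defaults describe a *high-SNR validation subject*:
the generator's contract (exercised by the test suite) is that its default
subject supports > 90 % online recall at < 15 % FAR, and that 240-epoch
grand averages recover the configured peak amplitudes to about 0.1 uV.
Real resting EEG carries far more low-frequency (delta/theta) power; you
can emulate that by raising `pink_fraction`, at the cost of grand-average
precision and detection performance — which is exactly the degradation a
real system faces.  Passing tests on the default subject therefore
validates the *pipeline machinery*, not biological effect sizes.

### Artifacts and keypresses

Blinks (Poisson, default 12/min, 150 uV, 0.3 s) load on the EOG channels
and the frontal pole; bursts (1/min, 300 uV, 20–60 Hz) hit one to three
random channels.  Both are sized to trip the 100-uV epoch rejection if left
uncleaned, so the ICA and ASR stages have real work to do.  Keypresses
follow each emergency onset at a log-normal reaction delay (median 0.6 s),
since the source experiment does not report reaction times separately.

## The preprocessing chain

The chain order is fixed — downsample, trailing baseline, ICA, ASR,
band-pass — and every stage is causal or fit-on-train-only, so the online
path never sees future samples:

1. **Downsampling** 1000 → 200 Hz: causal 8th-order Butterworth anti-alias
   low-pass at 80 Hz, then decimation; event onsets are rescaled.
2. **Baseline**: each sample minus the mean of the preceding 100 samples
   (0.5 s at 200 Hz).  A trailing window is the only causal reading of a
   sliding baseline compatible with streaming.
3. **ICA**: FastICA (symmetric fixed point, tanh contrast, seeded random
   orthonormal initialisation) on the scalp channels; components whose
   absolute correlation with either EOG channel exceeds 0.7 are removed.
   The unmixing matrix fit on training data is applied verbatim to test and
   online data.
4. **ASR**: calibration on the cleanest ~60 s of training data defines
   principal axes and per-component block-RMS thresholds
   (mean + 20 SD); at run time each 0.5-s block's component amplitudes are
   clamped to the thresholds.  Blocks are independent given the
   calibration, so the operation is streaming-safe.
5. **Band-pass**: causal fourth-order Butterworth, 0.1–5 Hz, per channel.
   Causal filtering is used on both the offline and online paths for
   train/test consistency.  Filters are initialised at the steady state of
   the first sample, suppressing onset transients, and their state is
   carried across streaming chunks so that chunked and batch application
   agree sample-exactly (this is asserted in the tests).

Whether the 100-uV rejection applies before or after filtering is not
fixed by the protocol; it is applied after the full chain here.

Two measurement paths share this machinery:

* the **detection path** uses the full causal chain above;
* the **ERP quantification path** (grand averages, peak tables) uses the
  amplitude-preserving stages only (downsample, ICA, ASR) plus a
  zero-phase 5 Hz low-pass before peak picking.  The causal baseline and
  band-pass would attenuate a 0.18-s-wide slow component by tens of
  percent and delay it; peak amplitudes measured after them would not be
  comparable to the configured template values.

## The decoder (HDCA)

Each 0.5-s training epoch — `[-3, -2.5]` s before an emergency onset as
the *normal* class, `[-0.25, 0.25]` s around it as the *emergency* class —
is divided into four 125-ms windows, and each window is reduced to its
per-channel mean amplitude `x[i, n]`.  Stage one learns one Fisher
discriminant per window,

  y_n = sum_i w[i, n] x[i, n],

compressing 37 channels into one score per window; stage two is a second
Fisher discriminant over the four window scores.  The label is
emergency when the stage-two score exceeds the midpoint of the two class
score means; ties go to the normal class (favouring low FAR).  Training
weights are reused verbatim at test time.

Three numerical choices matter:

* **Shrinkage.**  Per-window covariances (37 channels from at most ~200
  trials per class) are Ledoit–Wolf-shrunk toward a scaled identity.
* **Continuous background covariance.**  When the continuous training
  recording is available, `background_covariance()` estimates the
  within-class covariance from thousands of quiet 125-ms windows (stimulus
  neighbourhoods excluded) instead of the training epochs alone.  With 37
  channels, epoch-only covariance estimation costs roughly half of the
  achievable discriminability (measured against the Bayes-optimal linear
  discriminant on generator data); the continuous estimate recovers most
  of it.  A 5 % diagonal ridge keeps directions emptied by the ICA
  projection invertible.
* **Cross-fitted second stage.**  Stage-one scores computed on their own
  training data are optimistically separated, and a threshold placed at
  their midpoint does not transfer to out-of-sample data (we measured a
  systematic offset of more than half a standard deviation on streamed
  scores).  `fit_hdca` therefore refits stage one with each internal fold
  held out and trains stage two and the threshold on the held-out
  projections (stacking).  Set `crossfit = 0` to disable.

Comparators (`flat_lda`, a single discriminant on the concatenated
window-by-channel features, and `linear_svm`) run under the identical
cross-validation harness: stratified 5-fold, 10 cycles, cycle seeds
`seed + cycle`, with ICA/ASR/band-pass refit inside each training fold when
`fold_preproc` is supplied.  Recall is the emergency-class true positive
rate, FAR the normal-class false positive rate, and accuracy their
symmetric mean `(recall + (100 - FAR)) / 2` — the same identity used by the
online scoring, so offline and online numbers are directly comparable.

## The online protocol

`stream_decode` replays a raw recording on a virtual clock.  Every 200 ms
the newly arrived samples pass through the causal chain (with carried
filter state; the ICA projection is memoryless; ASR clamps per chunk), and
once one second of buffer exists the most recent 500 ms — matching the
trained 4 × 125 ms geometry — is classified, emitting one command.  Two
consecutive emergency commands constitute a detection (the time of the
second, confirming command), after which detections are suppressed for a
1-s refractory period.  Scoring follows the standard definitions: recall is
the percentage of emergency events with a detection within 1 s of onset;
FAR is the percentage of emergency-labelled commands among commands issued
in normal stages (outside `[onset, onset + 1 s]` of every emergency);
response time is detection time minus onset.  The "normal stages" reading
is the only one that keeps recall and FAR disjoint.  The minimum possible
response time is one command period after the first post-onset command
slot, i.e. the confirmation lag.

`run_online_experiment` mirrors the two-session protocol: 10 offline runs
are generated and used to fit the preprocessing state and the model, then
10 online runs are streamed and scored.

## Statistics

Peaks are measured per subject on (optionally 5-Hz zero-phase smoothed)
grand averages; the default search windows bracket the nominal latencies
(POz negative [0, 0.5] s, POz positive [0, 0.8] s, Fz negative
[0.2, 1.0] s).  Group comparisons use the two-sided Wilcoxon rank-sum test
(exact for group sizes up to 10 without ties; normal approximation with
mid-rank tie correction otherwise) and the two-sided sign-flip permutation
paired t-test (exact enumeration of all 2^n sign patterns for n <= 12
pairs, Monte-Carlo with the add-one estimator otherwise), with
Benjamini–Hochberg FDR adjustment across multiple comparisons.

## Problem sizes used by the test-suite

The full paradigm (20 runs, 47 minutes of 39-channel data at 1 kHz) is
exercised where the claim depends on it — the 240-epoch counts and the
grand-average peak recovery — and everywhere else the suite uses scaled
sessions (1–2 runs, 400–500 Hz) and direct feature-level fixtures, which
probe the same code paths at a fraction of the cost.  The type-I
calibration of the two tests runs 1000 replicates of an 8-vs-8 subject
comparison with identical (null) templates at miniature epoch counts.

## Known limitations

* The generator's background is stationary and its ERP components are
  deterministic across trials; real EEG has latency jitter, amplitude
  variability, non-stationary rhythms and much stronger low-frequency
  power.  Passing the generator contract does not certify performance on
  real recordings.
* ASR here is a principled simplification (per-block PCA clamp against
  calibration thresholds), not a reimplementation of the full
  sliding-window reconstruction algorithm.
* Gaussian envelopes have small pre-onset tails (about 0.1 uV for the
  widest components); they are a modelling artifact, not anticipation.
* Source-space analysis (head models, inverse imaging) is out of scope.
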