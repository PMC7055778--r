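---
title: "Detecting the end of postictal EEG suppression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the end of postictal EEG suppression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgesr)
```

## The problem

Postictal generalized EEG suppression (PGES) is a period of diffuse scalp-EEG
attenuation (background activity below 10 µV) that frequently follows a
generalized tonic–clonic seizure. Its duration is of clinical interest as a
candidate biomarker of SUDEP risk, and the quantity that determines the
duration is the *end* of suppression: the onset of the first intermittent
slow wave (ISW), the earliest recovering 0.5–5 Hz activity. Visual
annotation of this onset is slow and complicated by high-amplitude
physiological artifacts (movement, breathing, muscle) that mimic recovering
activity. `pgesr` implements an automated detector of the first-ISW onset
from 8-channel postictal EEG, together with the evaluation machinery that
such a detector needs.

The detector is a pipeline of five stages:

1. **Signal input** — EDF recordings are reduced to a fixed bipolar montage
   of 8 channels (Fp1-F7, F7-T7, T7-P7, Fp2-F8, F8-T8, T8-P8, Fz-Cz, Cz-Pz)
   and cut to the 5-minute postictal window starting at the seizure end
   `t0`.
2. **Preprocessing** — zero-phase band-pass to 0.5–5 Hz, then 1-second
   non-overlapping epochs.
3. **Features** — 76 features per channel per epoch (16 time-domain, 4
   band powers, 56 wavelet statistics) plus 4 interchannel correlations:
   612 values per epoch.
4. **Classification** — a bagged random forest of 1000 trees emits a
   per-epoch probability of ISW, thresholded at 0.5.
5. **Correction and read-out** — three confidence-based rules remove
   isolated, temporally unsupported ISW detections; the detected PGES end
   is the index of the first remaining ISW epoch.

## Preprocessing choices

The band filter is a 4th-order Butterworth applied forward and backward
(`signal::filtfilt`), so the response is zero-phase: a causal filter's group
delay would systematically shift the detected onset. The filter is applied
to the continuous 5-minute window *before* epoching; filtering each 1-second
epoch separately would introduce edge transients into exactly the short
segments the features are computed from.

Epochs are half-open intervals `[i, i+1)` seconds with epoch 0 starting at
`t0`, and a trailing partial second is discarded rather than padded. All
onsets (annotated and detected) are therefore whole seconds — the detector's
native resolution is the epoch length.

## The feature set

For each epoch and channel, three families:

* **Time-domain (16).** Mean, median, max, min, range, population standard
  deviation, the 5th/25th/75th/95th percentiles (linear interpolation
  between order statistics), RMS, kurtosis and skewness (standardized 4th
  and 3rd central moments, population convention), Hjorth mobility and
  complexity, and the amplitude energy `AE = Σ xᵢ²`. Mobility is
  `sqrt(var(d)/var(x))` with `dᵢ = xᵢ − xᵢ₋₁`, and complexity is the
  mobility of `d` divided by the mobility of `x` — first-difference
  estimates of mean frequency and waveform complexity.
* **Band powers (4).** Spectral power in 0.5–1, 1–2, 2–4 and 4–5 Hz. A
  1-second window cannot natively resolve the 0.5–1 Hz band, so the
  periodogram is computed on the epoch zero-padded to 8× its length and
  integrated over the band edges. This is a deterministic, leakage-accepting
  short-window estimate; the bands are features for a classifier, not
  calibrated spectral densities.
* **Wavelet (56).** A three-level Daubechies-4 decomposition under
  symmetric (half-sample) boundary extension yields coefficient sets cA3,
  cD3, cD2, cD1; each contributes the 14 statistical measures (the
  time-domain set minus range and AE). The boundary mode matters for
  reproducibility and is fixed and tested against reference coefficient
  vectors; the transform passes a perfect-reconstruction check.

Across channels, 4 Pearson correlations — (Fp1-F7, Fp2-F8), (Fp2-F8,
Fz-Cz), (Fp1-F7, Fz-Cz), (Fz-Cz, Cz-Pz) — capture the spatial coherence of
recovering slow waves, which suppressed noise lacks. Correlations are
computed on the filtered signal, consistent with every other feature.

**Degenerate epochs.** Suppressed EEG can be numerically constant after
quantization. Any measure that divides by a variance (mobility, complexity,
skewness, kurtosis, correlation) is defined as 0 for a zero-variance
series, so suppressed epochs never produce missing values.

## Classifier

A probability forest ([ranger]) of `n_trees = 1000` CART trees, Gini
splits, `mtry = floor(sqrt(612)) = 24` features per split, each tree grown
on a bootstrap resample. The prediction is the average of per-tree leaf
class fractions, i.e. `P(ISW)` per epoch; the out-of-bag samples give an
internal error estimate, so no nested cross-validation is used for model
assessment.

One departure from fully grown trees: the default depth cap is
`max_depth = 12`. ISW activity is *intermittent* — the seconds between
slow-wave bursts carry ISW training labels but suppression-like signal —
so fully grown trees spend most of their depth memorizing this label noise.
At depth 12 the out-of-bag error is within half a percentage point of
unlimited-depth forests on synthetic data while the ensemble is several
times cheaper to train; the cap is exposed as a parameter (`max_depth = 0`
restores unlimited growth).

**Balanced training sets.** Per recording with onset at `t` seconds: the
`min(t, 30)` epochs after the onset are the ISW examples (recovering
activity may end or change character; only the window right after the
onset is reliably ISW-like), and the equal number of epochs *immediately
before* the onset are the PGES examples — the hardest negatives, and the
ones that matter for localizing the transition. Recordings with onset at
epoch 0 contribute nothing and are excluded with a warning.

## Correction rules

The forest judges epochs independently, but suppression rarely resumes
once slow waves appear, so isolated ISW detections are suspicious. With
`prob` the forest output and `conf` the forward moving average of `prob`
over the current and next `M = 5` epochs, an epoch labeled ISW is
relabeled PGES when:

1. its probability is high (≥ `hi`) but both neighbors' probabilities are
   low (< `lo`);
2. its confidence is high but both neighbors' confidences are low;
3. its probability is high but its own confidence is low.

`hi = lo = 0.5` by default, symmetric with the classification threshold.
The rules are evaluated in one pass over a frozen copy of the inputs (no
cascading within the pass), neighbors are the immediate epochs `i−1` and
`i+1`, and at the sequence boundaries the missing-neighbor comparison is
skipped. The confidence window is truncated at the sequence end and
normalized by its actual length, keeping `conf` in `[0, 1]` everywhere;
over interior epochs it averages `M + 1` terms. Because every rule only
turns ISW into PGES, correction can only move the detected onset later —
a tested invariant.

## Evaluation

Segment-based accuracy misrepresents onset detection: a sequence with
29/30 epochs correct can still put the onset 15 s early if its single
error precedes the true onset. The recording-level metrics are therefore
primary:

* **TD** — predicted time distance, `|predicted − annotated|` onset in
  seconds. A recording with no detected ISW has undefined TD and counts as
  a miss at every tolerance (it stays in every denominator).
* **PPR_5s** — fraction of recordings with TD ≤ 5 s (tolerance
  configurable).

Segment metrics (accuracy, recall, precision, F1 with PGES as the positive
class, zero-denominator ratios defined as 0) are reported for comparison.

Cross-validation splits *recordings*, never epochs: training on any epoch
of a test recording would leak the very transition being detected. The
harness runs `folds = 10` over `repeats = 10` re-randomized partitions,
computes per-repeat metrics (segment metrics pooled over the repeat's test
epochs), and averages over repeats. Artifact groups are nested: A =
artifact-free, B = A + mild, C = B + moderate, D = all.

## The synthetic generator

Clinical postictal recordings with expert annotations are not publicly
available, so the package ships a generator that emulates the structure
the detector keys on:

* **Suppression**: independent per-channel Gaussian noise, RMS equal to
  `suppression_amplitude` (default 5 µV, satisfying the < 10 µV criterion).
* **ISW**: from the annotated onset, Hann-windowed sinusoidal bursts
  (frequency drawn per burst from 0.5–5 Hz, duration 1.5–3 s, gaps
  0.5–2 s, peak amplitude `isw_amplitude`, default 40 µV) shared across
  channels with per-channel gains in 0.7–1.3 — so interchannel
  correlations are genuinely informative. The first burst starts exactly
  at the onset, which keeps the annotation recoverable by a simple
  amplitude oracle (a tested generator invariant).
* **Artifacts**: damped slow oscillations plus a decaying offset, 5–20×
  the ISW amplitude, graded by the four-tier scheme in which the midline
  channels (Fz-Cz, Cz-Pz) are pivotal: *mild* transients involve only
  non-midline channels; *moderate* adds sub-second transients touching a
  midline channel; *severe* adds transients longer than 1 s covering both
  midline channels. Tiers are cumulative, and each contaminated recording
  gets at least one transient during the suppression period — artifacts
  that mimic recovery where there is none are the clinically confounding
  case.

Dataset-level parameters (artifact mix — default mirroring a 116-recording
clinical composition of 27/31/25/33 across the four tiers — onsets uniform
over 20–90 s in whole seconds, per-recording amplitudes) are drawn from a
master seed; each recording is then generated from its own derived seed,
so datasets are reproducible as a whole and per recording. The default
sampling rate is 256 Hz, typical of epilepsy-monitoring-unit scalp EEG;
every pipeline stage is rate-agnostic.

**What passing on synthetic data does and does not show.** The generator
reproduces amplitude contrast, band content, intermittency, spatial
coherence and graded artifact contamination — enough to exercise every
pipeline stage and to show that the detector recovers known onsets and
degrades under artifacts. It does not model real postictal dynamics
(evolving slow-wave morphology, electrode artifacts, drowsiness patterns,
line noise), so synthetic performance figures say nothing quantitative
about clinical recordings.

## Numerical conventions worth knowing

* EDF samples are 16-bit; the writer picks a symmetric physical range per
  channel, so round-trip error is bounded by half a quantization step.
* Percentiles interpolate linearly between order statistics (type 7).
* The classification threshold ties (`prob == 0.5`) go to ISW.
* Band powers use a one-sided periodogram excluding DC; the four-band sum
  is bounded by the signal's mean square (Parseval), a tested property.
* All stochastic components (generator, forest, fold assignment) take
  explicit seeds; derived seeds stay below 2³¹.

## Problem sizes used in the shipped tests

The test-suite evaluation runs use 60 artifact-free recordings evaluated
at 10-fold cross-validation with a single repeat and 1000-tree forests;
the nested artifact groups (15 mild, 15 moderate and 15 severe recordings
added in turn) are evaluated at 5 folds, since the artifact-degradation
comparison is a recording-level property that does not need the finer
partition. Unit tests use smaller 2-minute recordings. These sizes were
chosen as the smallest at which recording-level rates are stable enough to
be meaningful; the cross-validation harness itself defaults to 10 repeats
for real use.

## Known limitations

* The detector assumes `t0` (seizure end) is given; it does not find it.
* Intracranial montages, video synchronization and automatic artifact
  removal are out of scope.
* On recordings whose true onset falls outside the 5-minute window, or
  whose suppression amplitude approaches the ISW amplitude, detection is
  undefined or unreliable by construction.
* The correction rules are a single pass; they do not iterate to a fixed
  point, and they cannot repair *sustained* artifact-driven false ISW runs
  (severe artifacts) — by design, matching the method's stated behavior of
  degrading with artifact level.
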