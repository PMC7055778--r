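# pgesr

Automated detection of the end of postictal generalized EEG suppression
(PGES) from 8-channel scalp EEG.

After a generalized tonic–clonic seizure, the scalp EEG often shows a
period of diffuse background attenuation below 10 µV — PGES — whose
duration is a candidate biomarker of SUDEP risk. The clinically relevant
event is the *end* of suppression: the onset of the first intermittent
slow wave (ISW), the earliest recovering 0.5–5 Hz activity. `pgesr` is for
researchers analyzing epilepsy-monitoring-unit recordings who need that
onset annotated automatically and evaluated with metrics that reflect how
annotation errors propagate into PGES-duration estimates.

## Method

The detector classifies every 1-second epoch of the 5-minute postictal
window as PGES (0) or ISW (1) and reports the first ISW epoch:

* **Montage and preprocessing.** EDF input is reduced to the bipolar
  channels Fp1-F7, F7-T7, T7-P7, Fp2-F8, F8-T8, T8-P8, Fz-Cz, Cz-Pz;
  zero-phase band-pass 0.5–5 Hz; non-overlapping 1-s epochs.
* **Features (612 per epoch).** Per channel: 16 time-domain measures
  (including Hjorth mobility `sqrt(var(Δx)/var(x))` and complexity, and
  amplitude energy `Σxᵢ²`), spectral power in 0.5–1 / 1–2 / 2–4 / 4–5 Hz,
  and 14 statistics of each set of a three-level Daubechies-4 wavelet
  decomposition; plus 4 interchannel Pearson correlations.
* **Classifier.** A bagged random forest, *N* = 1000 trees, `mtry = √p`;
  the per-epoch ISW probability is the average of tree outputs, with
  out-of-bag error as the internal performance estimate.
* **Correction rules.** With `conf(Segᵢ)` the mean probability of the
  current and next *M* = 5 segments, an ISW-labeled epoch is relabeled
  PGES when its probability (or confidence) is an isolated spike relative
  to its neighbors, or when a high probability lacks confidence support.
  Corrections only ever move the detected onset later.
* **Evaluation.** Per recording, the predicted time distance
  `TD = |predicted − annotated onset|`; over a dataset, `PPR_5s`, the
  fraction of recordings with TD ≤ 5 s, alongside segment-based accuracy /
  recall / precision / F1 (PGES positive). Cross-validation always splits
  by recording, with nested artifact groups A (artifact-free) through D
  (all severities).

Clinical recordings with expert annotations are not publicly available,
so the package includes a synthetic postictal EEG generator (suppression
noise, intermittent shared slow-wave bursts, four graded tiers of
movement-like artifact transients keyed on the midline channels) that
every stage is tested against. See the methods vignette
(`vignettes/pges-detection-methods.Rmd`) for the model, conventions and
design decisions.

## Worked example

```r
library(pgesr)

# 12 artifact-free synthetic recordings, 2 minutes each
recs <- generate_dataset(12, level_mix = c(free = 1, mild = 0,
                                           moderate = 0, severe = 0),
                         onset_range = c(15, 50), seed = 3, duration = 120)
feats <- pges_features_dataset(recs)      # 12 x 120 epochs x 612 features
ann <- dataset_annotations(recs)

ts <- build_training_set(feats, ann)      # balanced PGES/ISW segments
model <- pges_rf(ts, n_trees = 200, seed = 5)
glance(model)
#> # A tibble: 1 × 5
#>   n_trees  mtry n_train oob_error oob_brier
#>     <dbl> <dbl>   <int>     <dbl>     <dbl>
#> 1     200    24     598    0.0669    0.0579

# detect the PGES end of one recording
det <- detect_pges_end(model, dplyr::filter(feats, recording_id == "rec001"))
det$predicted_onset
#> [1] 22
ann$isw_onset_seconds[1]
#> [1] 22
```

The out-of-bag error (~6.7%) is dominated by post-onset epochs that fall
in the gaps between slow-wave bursts; the recording-level onset is still
recovered exactly because the first burst epoch is classified with high
probability and survives the correction rules.

Cross-validated evaluation of a dataset:

```r
ev <- cross_validate(feats, ann, folds = 4, repeats = 2, group = "A",
                     n_trees = 200, seed = 19)
glance(ev)      # ppr, mean_td, accuracy, recall, precision, f1
autoplot(ev)    # histogram of per-recording time distances
```

A command-line front end (`exec/pges.R`) exposes the same pipeline as
`simulate`, `train`, `detect` and `evaluate` subcommands over directories
of EDF files with an `annotations.csv` sidecar.

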