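# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 12 artifact-free 2-minute recordings with features and annotations:
# big enough to train on, small enough for unit tests
fx_clean_set <- function() {
  fixture("clean_set", function() {
    recs <- generate_dataset(12, level_mix = c(free = 1, mild = 0,
                                               moderate = 0, severe = 0),
                             onset_range = c(15, 50), seed = 3, duration = 120)
    feats <- pges_features_dataset(recs)
    list(recordings = recs, features = feats,
         annotations = dataset_annotations(recs))
  })
}

# a model trained on the clean set
fx_clean_model <- function() {
  fixture("clean_model", function() {
    fx <- fx_clean_set()
    ts <- build_training_set(fx$features, fx$annotations)
    pges_rf(ts, n_trees = 200, seed = 5)
  })
}

# separable two-feature training tibble using real feature names
fx_separable <- function(n = 200, gap = 4, seed = 1) {
  set.seed(seed)
  lab <- rep(0:1, each = n / 2)
  tibble::tibble(
    `Fp1-F7.mean` = rnorm(n) + gap * lab,
    `Fp1-F7.std` = rnorm(n),
    label = lab
  )
}

# a tiny referential recording: constant per-electrode values
fx_referential_recording <- function(values, fs = 128, seconds = 4,
                                     labels = NULL) {
  electrodes <- c("Fp1", "F7", "T7", "P7", "Fp2", "F8", "T8", "P8",
                  "Fz", "Cz", "Pz")
  if (is.null(labels)) labels <- electrodes
  n <- fs * seconds
  data <- vapply(values, function(v) rep(v, n), numeric(n))
  eeg_recording(data, fs = fs, channels = labels, t0 = 0)
}
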