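# Synthetic postictal EEG: a suppression period of low-amplitude broadband
# noise (< 10 uV, the PGES criterion), followed from the annotated onset by
# intermittent 0.5-5 Hz slow-wave bursts shared across channels, with
# optional high-amplitude movement-like transients graded into the four
# artifact tiers. Not a biophysical model -- it reproduces the amplitude,
# band and intermittency structure the detector keys on, nothing more.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic recording
#'
#' @param fs Sampling rate in Hz (default 256, typical EMU scalp EEG).
#' @param duration Recording length in seconds (default 300, the 5-minute
#'   postictal window).
#' @param pges_duration Suppression length in seconds; the first-ISW onset.
#' @param isw_amplitude Slow-wave burst peak amplitude in microvolts.
#' @param suppression_amplitude RMS of the suppression-period noise in
#'   microvolts; must be < 10 (the PGES amplitude criterion).
#' @param artifact_level `"free"`, `"mild"`, `"moderate"` or `"severe"`.
#' @param seed Integer seed; same spec, same seed, bit-identical recording.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(fs = 256, duration = 300, pges_duration = 60,
                           isw_amplitude = 40, suppression_amplitude = 5,
                           artifact_level = c("free", "mild", "moderate", "severe"),
                           seed = 1L) {
  artifact_level <- match.arg(artifact_level)
  if (suppression_amplitude >= 10) {
    abort("`suppression_amplitude` must be < 10 uV (the PGES criterion).",
          class = "pges_parameter_error")
  }
  if (isw_amplitude <= suppression_amplitude) {
    abort("`isw_amplitude` must exceed `suppression_amplitude`.",
          class = "pges_parameter_error")
  }
  if (!(pges_duration > 0 && pges_duration < duration)) {
    abort("Need 0 < pges_duration < duration.", class = "pges_parameter_error")
  }
  structure(list(fs = fs, duration = duration, pges_duration = pges_duration,
                 isw_amplitude = isw_amplitude,
                 suppression_amplitude = suppression_amplitude,
                 artifact_level = artifact_level, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# add a waveform to selected channels with per-channel gains
add_event <- function(data, fs, t_start, wave, channels, gains) {
  i0 <- round(t_start * fs) + 1
  i1 <- min(i0 + length(wave) - 1, nrow(data))
  if (i1 < i0) return(data)
  w <- wave[seq_len(i1 - i0 + 1)]
  for (k in seq_along(channels)) {
    data[i0:i1, channels[k]] <- data[i0:i1, channels[k]] + w * gains[k]
  }
  data
}

# movement-like transient: damped slow oscillation plus a decaying offset
artifact_wave <- function(fs, dur, amp) {
  tt <- seq(0, dur, by = 1 / fs)
  f <- runif(1, 1, 4)
  phase <- runif(1, 0, 2 * pi)
  amp * (0.7 * exp(-2.5 * tt / dur) * sin(2 * pi * f * tt + phase) +
           0.3 * exp(-4 * tt / dur))
}

#' Generate one annotated synthetic postictal recording
#'
#' Before the onset: independent per-channel Gaussian noise with RMS equal
#' to `suppression_amplitude`. From the onset (where the first burst starts
#' exactly): Hann-windowed sinusoidal bursts, frequency drawn per burst from
#' 0.5-5 Hz, 1.5-3 s long with 0.5-2 s gaps, shared across channels with
#' per-channel gains (so interchannel correlations are informative), on top
#' of continuing noise. Artifact transients (5-20x the ISW amplitude,
#' damped oscillation plus offset) are injected according to the tier:
#' mild involves only non-midline channels; moderate adds sub-second
#' transients on a midline channel; severe adds >1 s transients covering
#' both midline channels (and the rest). Each tier guarantees at least one
#' transient during the suppression period -- the clinically confounding
#' case.
#'
#' @param spec A [synthetic_spec()].
#' @param id Recording identifier.
#' @return An [eeg_recording()] with `annotation = pges_duration`.
#' @export
generate_recording <- function(spec, id = sprintf("synth-%d", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    fs <- spec$fs; dur <- spec$duration; onset <- spec$pges_duration
    n <- round(fs * dur)
    data <- matrix(rnorm(n * 8, sd = spec$suppression_amplitude), n, 8)
    colnames(data) <- pges_channels()

    # intermittent slow-wave bursts from the onset onwards
    t <- onset; first <- TRUE
    while (t < dur - 0.2) {
      b_dur <- runif(1, 1.5, 3)
      f <- if (first) runif(1, 1, 3) else runif(1, 0.5, 5)
      phase <- runif(1, 0, 2 * pi)
      tt <- seq(0, b_dur, by = 1 / fs)
      env <- 0.5 * (1 - cos(2 * pi * tt / b_dur))           # Hann
      wave <- spec$isw_amplitude * env * sin(2 * pi * f * tt + phase)
      data <- add_event(data, fs, t, wave, 1:8, runif(8, 0.7, 1.3))
      t <- t + b_dur + runif(1, 0.5, 2)
      first <- FALSE
    }

    # artifact schedule: tiers are cumulative, matching the nested grading
    lvl <- match(spec$artifact_level, c("free", "mild", "moderate", "severe"))
    place <- function(k, force_pre) {
      # k start times; the first is forced into the suppression period
      starts <- runif(k, 2, dur - 4)
      if (force_pre && onset > 8) starts[1] <- runif(1, 2, onset - 4)
      starts
    }
    if (lvl >= 2) {                                         # mild tier
      starts <- place(4, TRUE)
      for (s in starts) {
        d <- runif(1, 0.4, 0.9)
        chs <- sample(1:6, sample(1:2, 1))
        data <- add_event(data, fs, s, artifact_wave(fs, d, runif(1, 5, 20) * spec$isw_amplitude),
                          chs, runif(length(chs), 0.8, 1.2))
      }
    }
    if (lvl >= 3) {                                         # moderate tier
      starts <- place(3, TRUE)
      for (s in starts) {
        d <- runif(1, 0.4, 0.9)
        chs <- c(sample(7:8, 1), sample(1:6, 2))
        data <- add_event(data, fs, s, artifact_wave(fs, d, runif(1, 5, 20) * spec$isw_amplitude),
                          chs, runif(length(chs), 0.8, 1.2))
      }
    }
    if (lvl >= 4) {                                         # severe tier
      starts <- place(2, TRUE)
      for (s in starts) {
        d <- runif(1, 1.4, 2.8)
        data <- add_event(data, fs, s, artifact_wave(fs, d, runif(1, 5, 20) * spec$isw_amplitude),
                          1:8, runif(8, 0.8, 1.2))
      }
    }

    eeg_recording(data, fs = fs, t0 = 0, annotation = onset, id = id,
                  artifact_level = spec$artifact_level)
  })
}

#' Generate an annotated synthetic dataset
#'
#' Recording-level parameters (artifact level per the mix, onset uniform
#' over `onset_range` in whole seconds, per-recording suppression and
#' slow-wave amplitudes) are drawn from the master seed; each recording is
#' then generated from its own derived seed, so the dataset is reproducible
#' as a whole and per recording.
#'
#' @param n Number of recordings.
#' @param level_mix Named proportions (or counts) over
#'   free/mild/moderate/severe; default mirrors the 27/31/25/33 composition
#'   of a 116-recording clinical study population.
#' @param onset_range Two integers: inclusive range of onsets in seconds.
#' @param seed Master seed.
#' @param fs,duration Passed to every [synthetic_spec()].
#' @return List of [eeg_recording()] objects.
#' @export
generate_dataset <- function(n, level_mix = c(free = 27, mild = 31,
                                              moderate = 25, severe = 33),
                             onset_range = c(20, 90), seed = 1L,
                             fs = 256, duration = 300) {
  if (n < 1) abort("`n` must be >= 1.", class = "pges_parameter_error")
  if (onset_range[2] >= duration) {
    abort(sprintf("`onset_range` upper end (%g s) must lie inside the %g-s recording.",
                  onset_range[2], duration), class = "pges_parameter_error")
  }
  lv <- c("free", "mild", "moderate", "severe")
  mix <- level_mix[lv]
  if (anyNA(mix)) abort("`level_mix` must name all four levels.",
                        class = "pges_parameter_error")
  mix <- mix / sum(mix)
  local_seed(seed, {
    levels <- sample(lv, n, replace = TRUE, prob = mix)
    onsets <- sample(seq(onset_range[1], onset_range[2]), n, replace = TRUE)
    supp <- runif(n, 3, 8)
    isw <- runif(n, 25, 60)
    seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% 2147483647L
    lapply(seq_len(n), function(i) {
      generate_recording(
        synthetic_spec(fs = fs, duration = duration, pges_duration = onsets[i],
                       isw_amplitude = isw[i], suppression_amplitude = supp[i],
                       artifact_level = levels[i], seed = seeds[i]),
        id = sprintf("rec%03d", i))
    })
  })
}

#' Annotation table of a list of recordings
#'
#' @param recordings List of [eeg_recording()] objects.
#' @return Tibble with `recording_id`, `t0_seconds`, `isw_onset_seconds`,
#'   `artifact_level` -- the sidecar format of [read_annotations()].
#' @export
dataset_annotations <- function(recordings) {
  tibble::tibble(
    recording_id = vapply(recordings, function(r) r$id, ""),
    t0_seconds = vapply(recordings, function(r) r$t0, 0),
    isw_onset_seconds = vapply(recordings, function(r) r$annotation, 0),
    artifact_level = vapply(recordings, function(r) r$artifact_level, "")
  )
}
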