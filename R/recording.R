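#' Construct an EEG recording
#'
#' The in-memory container used throughout the pipeline: a samples-by-channels
#' matrix of scalp potentials in microvolts, a sampling rate, and the time
#' reference of the analysis (`t0`, the seizure end, in seconds from the start
#' of `data`). An optional expert annotation gives the onset of the first
#' intermittent slow wave (ISW) in seconds after `t0`.
#'
#' @param data Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz; must exceed 10 Hz so that the 0.5-5 Hz band
#'   of interest is representable.
#' @param channels Character vector of channel labels; defaults to the
#'   canonical 8 bipolar labels of [pges_channels()].
#' @param t0 Seizure-end time in seconds from the start of `data`.
#' @param annotation Optional first-ISW onset in seconds after `t0`, or `NA`.
#' @param id Optional recording identifier.
#' @param artifact_level One of `"free"`, `"mild"`, `"moderate"`, `"severe"`,
#'   or `NA` when ungraded.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = pges_channels(), t0 = 0,
                          annotation = NA_real_, id = NA_character_,
                          artifact_level = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 10) {
    abort("`fs` must be a single number > 10 Hz.", class = "pges_parameter_error")
  }
  if (ncol(data) != length(channels)) {
    abort(sprintf("`data` has %d columns but %d channel labels were given.",
                  ncol(data), length(channels)),
          class = "pges_channel_error")
  }
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels, t0 = t0,
         annotation = annotation, id = id, artifact_level = artifact_level),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$fs
  cat(sprintf("<eeg_recording> %s\n", ifelse(is.na(x$id), "(unnamed)", x$id)))
  cat(sprintf("  %d channels x %.1f s @ %g Hz (t0 = %g s)\n",
              ncol(x$data), dur, x$fs, x$t0))
  if (!is.na(x$annotation)) {
    cat(sprintf("  annotated first-ISW onset: %g s after t0\n", x$annotation))
  }
  if (!is.na(x$artifact_level)) {
    cat(sprintf("  artifact level: %s\n", x$artifact_level))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$data) / rec$fs
}

#' Convert a recording to a long tibble
#'
#' One row per sample per channel, for plotting or export.
#'
#' @param x An [eeg_recording()].
#' @param ... Unused.
#' @return A tibble with columns `time` (s, relative to file start),
#'   `channel`, `amplitude` (microvolts).
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  n <- nrow(x$data)
  tibble::tibble(
    time = rep(seq_len(n) - 1, times = ncol(x$data)) / x$fs,
    channel = factor(rep(x$channels, each = n), levels = x$channels),
    amplitude = as.vector(x$data)
  )
}

#' Plot a recording as stacked channel traces
#'
#' @param object An [eeg_recording()].
#' @param ... Unused.
#' @return A ggplot object; the annotated first-ISW onset (if any) is drawn
#'   as a dashed vertical line.
#' @export
autoplot.eeg_recording <- function(object, ...) {
  df <- as_tibble.eeg_recording(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V)")),
                  title = object$id) +
    ggplot2::theme_minimal()
  if (!is.na(object$annotation)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t0 + object$annotation,
                                 linetype = "dashed", colour = "red")
  }
  p
}
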