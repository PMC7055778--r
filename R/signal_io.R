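#' Extract the postictal analysis window
#'
#' Cuts the window `[t0, t0 + duration)` out of a recording and makes its
#' start the new time origin, so that epoch 0 of the downstream pipeline is
#' the first postictal second. An expert annotation given in absolute seconds
#' relative to the old origin is re-expressed relative to the window start.
#'
#' @param rec An [eeg_recording()].
#' @param t0 Window start in seconds from the start of `rec` (defaults to the
#'   recording's own seizure-end mark).
#' @param duration Window length in seconds (default 300, the 5-minute
#'   postictal analysis window).
#' @return An [eeg_recording()] of length `duration` with `t0 = 0`.
#' @export
extract_postictal_window <- function(rec, t0 = rec$t0, duration = 300) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (duration <= 0) {
    abort("`duration` must be positive.", class = "pges_parameter_error")
  }
  n <- nrow(rec$data)
  i0 <- round(t0 * rec$fs)
  i1 <- i0 + round(duration * rec$fs)
  if (i0 < 0 || i1 > n) {
    abort(sprintf(
      "Window [%g, %g) s exceeds the %.1f s recording.",
      t0, t0 + duration, n / rec$fs), class = "pges_bounds_error")
  }
  ann <- rec$annotation
  if (!is.na(ann)) ann <- ann + rec$t0 - t0  # re-express relative to new origin
  eeg_recording(rec$data[(i0 + 1):i1, , drop = FALSE], fs = rec$fs,
                channels = rec$channels, t0 = 0, annotation = ann,
                id = rec$id, artifact_level = rec$artifact_level)
}
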