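# Preprocessing: restrict the signal to the 0.5-5 Hz band where PGES and ISW
# live, then cut it into 1-second non-overlapping epochs. Filtering is done on
# the continuous window, before epoching, so epochs carry no edge transients.

#' Band-pass filter a recording
#'
#' 4th-order Butterworth, applied forward and backward (zero phase), so the
#' filter delays nothing: onset timing is preserved. Default band 0.5-5 Hz,
#' the band of the slow activity that ends PGES.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Cutoff frequencies in Hz; `0 < low < high < fs/2`.
#' @param order Filter order (of the underlying one-way Butterworth).
#' @return The filtered [eeg_recording()], same length.
#' @export
eeg_bandpass <- function(rec, low = 0.5, high = 5, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    abort(sprintf("Band [%g, %g] Hz is invalid for fs = %g Hz (need 0 < low < high < fs/2).",
                  low, high, rec$fs), class = "pges_parameter_error")
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  colnames(out$data) <- rec$channels
  out
}

#' Split a recording into 1-second epochs
#'
#' Epochs are contiguous, non-overlapping, and half-open: epoch `i` covers
#' `[i, i+1)` seconds after the window origin, with epoch 0 starting at t0.
#' A trailing partial epoch is discarded. All detected onsets downstream are
#' whole seconds because they are epoch indices.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Epoch length in seconds (default 1).
#' @return An `eeg_epochs` object: an array `samples x channels x epochs`
#'   plus `fs`, `channels`, `origin` and the recording's annotation.
#' @export
eeg_epoch <- function(rec, epoch_seconds = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_seconds * rec$fs)
  n_ep <- nrow(rec$data) %/% len
  if (n_ep < 1) {
    abort(sprintf("Recording (%.2f s) is shorter than one %g-s epoch.",
                  nrow(rec$data) / rec$fs, epoch_seconds),
          class = "pges_parameter_error")
  }
  used <- rec$data[seq_len(n_ep * len), , drop = FALSE]
  arr <- array(0, dim = c(len, ncol(used), n_ep),
               dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_len(n_ep)) {
    arr[, , e] <- used[((e - 1) * len + 1):(e * len), ]
  }
  structure(
    list(epochs = arr, fs = rec$fs, channels = rec$channels,
         n_epochs = n_ep, epoch_seconds = epoch_seconds, origin = 0,
         annotation = rec$annotation, id = rec$id,
         artifact_level = rec$artifact_level),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs of %g s x %d channels @ %g Hz\n",
              x$n_epochs, x$epoch_seconds, length(x$channels), x$fs))
  invisible(x)
}
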