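# Per-epoch feature extraction. 76 features per channel -- 16 time-domain,
# 4 low-frequency band powers, 56 wavelet statistics -- plus 4 interchannel
# correlations: 8 x 76 + 4 = 612 features per 1-second epoch.
#
# All statistics use the population (1/N) moment convention. Degenerate
# (zero-variance) epochs are legitimate in suppressed EEG, so mobility,
# complexity, skewness, kurtosis and correlations involving a constant
# series are defined as 0 rather than NaN.

TD_MEASURES <- c("mean", "median", "max", "min", "range", "std",
                 "p05", "p25", "p75", "p95", "rms",
                 "kurtosis", "skewness", "mobility", "complexity", "ae")
WL_MEASURES <- setdiff(TD_MEASURES, c("range", "ae"))
BP_MEASURES <- c("bp_0.5_1", "bp_1_2", "bp_2_4", "bp_4_5")
WL_SETS <- c("cA3", "cD3", "cD2", "cD1")

CORR_PAIRS <- list(
  c("Fp1-F7", "Fp2-F8"),
  c("Fp2-F8", "Fz-Cz"),
  c("Fp1-F7", "Fz-Cz"),
  c("Fz-Cz", "Cz-Pz")
)

#' Names and order of the 612 feature columns
#'
#' Per channel (in canonical channel order): the 16 time-domain measures,
#' the 4 band powers, then 14 measures for each wavelet coefficient set
#' (cA3, cD3, cD2, cD1); finally the 4 interchannel correlations.
#'
#' @return Character vector of length 612.
#' @export
feature_columns <- function() {
  per_chan <- c(TD_MEASURES, BP_MEASURES,
                as.vector(t(outer(WL_SETS, WL_MEASURES, paste, sep = "_"))))
  c(as.vector(t(outer(pges_channels(), per_chan, paste, sep = "."))),
    vapply(CORR_PAIRS, function(p) paste0("corr.", p[1], "__", p[2]), ""))
}

# type-7 (linear interpolation) column quantiles of a sorted matrix
col_quantile_sorted <- function(S, p) {
  n <- nrow(S)
  h <- (n - 1) * p
  lo <- floor(h)
  g <- h - lo
  if (g == 0) S[lo + 1, ] else S[lo + 1, ] * (1 - g) + S[lo + 2, ] * g
}

col_pop_var <- function(X) colMeans(X^2) - colMeans(X)^2

# the 14/16 statistical measures for every column of X (samples x epochs);
# returns epochs x measures
epoch_stats <- function(X, full = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X)
  S <- apply(X, 2, sort)
  if (m == 1) S <- matrix(S, ncol = 1)
  xc <- X - rep(mu, each = n)
  m2 <- colMeans(xc^2)
  m3 <- colMeans(xc^3)
  m4 <- colMeans(xc^4)
  std <- sqrt(m2)
  D <- diff(X)
  if (m == 1) D <- matrix(D, ncol = 1)
  vd <- col_pop_var(D)
  DD <- diff(D)
  if (m == 1) DD <- matrix(DD, ncol = 1)
  vdd <- col_pop_var(DD)
  mob <- ifelse(m2 > 0, sqrt(vd / m2), 0)
  mob_d <- ifelse(vd > 0, sqrt(vdd / vd), 0)
  out <- cbind(
    mean = mu,
    median = col_quantile_sorted(S, 0.5),
    max = S[n, ],
    min = S[1, ],
    range = S[n, ] - S[1, ],
    std = std,
    p05 = col_quantile_sorted(S, 0.05),
    p25 = col_quantile_sorted(S, 0.25),
    p75 = col_quantile_sorted(S, 0.75),
    p95 = col_quantile_sorted(S, 0.95),
    rms = sqrt(colMeans(X^2)),
    kurtosis = ifelse(m2 > 0, m4 / m2^2, 0),
    skewness = ifelse(m2 > 0, m3 / m2^1.5, 0),
    mobility = mob,
    complexity = ifelse(mob > 0, mob_d / mob, 0),
    ae = colSums(X^2)
  )
  if (!full) out <- out[, WL_MEASURES, drop = FALSE]
  out
}

#' Time-domain features of a 1-second epoch
#'
#' The 16 time-domain measures: mean, median, max, min, range, standard
#' deviation (population), 5th/25th/75th/95th percentiles (linear
#' interpolation), RMS, kurtosis and skewness (standardized 4th and 3rd
#' central moments), Hjorth mobility and complexity (via first differences
#' `d_i = x_i - x_{i-1}`), and amplitude energy `AE = sum x_i^2`. A constant
#' epoch has mobility, complexity, skewness and kurtosis 0 by convention.
#'
#' @param x Numeric vector, length >= 4.
#' @return Named numeric vector of length 16.
#' @export
time_domain_features <- function(x) {
  if (length(x) < 4) {
    abort("Need at least 4 samples.", class = "pges_parameter_error")
  }
  drop(epoch_stats(matrix(x, ncol = 1)))
}

# band powers for all columns of X; returns epochs x 4
band_powers_mat <- function(X, fs) {
  X <- as.matrix(X)
  n <- nrow(X)
  npad <- 8L * n
  P <- rbind(X, matrix(0, npad - n, ncol(X)))
  F <- stats::mvfft(P)
  pw <- Mod(F)^2 * (2 / (npad * n))        # one-sided periodogram, power units
  freq <- (seq_len(npad) - 1) * fs / npad
  half <- 2:(npad %/% 2)                    # positive frequencies, no DC
  f <- freq[half]
  pick <- function(lo, hi, closed) {
    sel <- half[f >= lo & (if (closed) f <= hi else f < hi)]
    if (length(sel) == 0) return(numeric(ncol(X)))
    colSums(pw[sel, , drop = FALSE])
  }
  out <- cbind(pick(0.5, 1, FALSE), pick(1, 2, FALSE),
               pick(2, 4, FALSE), pick(4, 5, TRUE))
  colnames(out) <- BP_MEASURES
  out
}

#' Low-frequency band powers of a 1-second epoch
#'
#' Spectral power in the four bands 0.5-1, 1-2, 2-4 and 4-5 Hz, estimated
#' from a periodogram zero-padded to 8x the epoch length so that a 1-second
#' window can resolve the 0.5-1 Hz band. Powers are in squared-amplitude
#' units; their total never exceeds the signal's mean square power
#' (Parseval).
#'
#' @param x Numeric vector (one epoch of one channel).
#' @param fs Sampling rate in Hz (>= 16).
#' @return Named numeric vector of length 4.
#' @export
band_powers <- function(x, fs) {
  if (fs < 16) abort("Need fs >= 16 Hz.", class = "pges_parameter_error")
  drop(band_powers_mat(matrix(x, ncol = 1), fs))
}

#' Wavelet features of a 1-second epoch
#'
#' Three-level db4 decomposition ([dwt_db4()]); for each of the four
#' coefficient sets (cA3, cD3, cD2, cD1) the 14 statistical measures (the
#' time-domain set minus range and AE). 4 x 14 = 56 values.
#'
#' @param x Numeric vector, length >= 32.
#' @return Named numeric vector of length 56.
#' @export
wavelet_features <- function(x) {
  cf <- dwt_db4(x)
  out <- unlist(lapply(WL_SETS, function(s) {
    v <- drop(epoch_stats(matrix(cf[[s]], ncol = 1), full = FALSE))
    names(v) <- paste(s, WL_MEASURES, sep = "_")
    v
  }))
  out
}

# Pearson correlation between fixed channel pairs for all epochs;
# A, B: samples x epochs. Zero-variance series correlate 0 by convention.
col_corr <- function(A, B) {
  n <- nrow(A)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colMeans(A^2) - ma^2
  vb <- colMeans(B^2) - mb^2
  cov <- colMeans(A * B) - ma * mb
  ifelse(va > 0 & vb > 0, cov / sqrt(va * vb), 0)
}

#' Interchannel correlations of a 1-second epoch
#'
#' Pearson linear correlation between the four fixed channel pairs:
#' (Fp1-F7, Fp2-F8), (Fp2-F8, Fz-Cz), (Fp1-F7, Fz-Cz), (Fz-Cz, Cz-Pz).
#' If either channel is constant within the epoch the correlation is 0 by
#' convention.
#'
#' @param epoch Numeric matrix, samples x channels, with the canonical
#'   channel labels as column names.
#' @return Named numeric vector of length 4, each in `[-1, 1]`.
#' @export
interchannel_correlations <- function(epoch) {
  epoch <- as.matrix(epoch)
  need <- unique(unlist(CORR_PAIRS))
  miss <- setdiff(need, colnames(epoch))
  if (length(miss)) {
    abort(sprintf("Epoch lacks channel(s): %s", paste(miss, collapse = ", ")),
          class = "pges_channel_error")
  }
  out <- vapply(CORR_PAIRS, function(p) {
    col_corr(epoch[, p[1], drop = FALSE], epoch[, p[2], drop = FALSE])
  }, numeric(1))
  names(out) <- vapply(CORR_PAIRS, function(p) paste0("corr.", p[1], "__", p[2]), "")
  out
}

#' Extract the full feature table of an epoched recording
#'
#' One row per epoch, 612 feature columns in the fixed order of
#' [feature_columns()], preceded by an `epoch` index column (0-based; equals
#' seconds after t0). Channels are matched by label, so a permuted input
#' channel order yields the same table.
#'
#' @param epochs An `eeg_epochs` object from [eeg_epoch()].
#' @return A tibble, `n_epochs` rows x (1 + 612) columns.
#' @export
extract_feature_table <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  arr <- epochs$epochs
  n <- dim(arr)[1]; m <- dim(arr)[3]
  blocks <- lapply(pges_channels(), function(ch) {
    X <- matrix(arr[, ch, ], nrow = n, ncol = m)
    td <- epoch_stats(X)
    bp <- band_powers_mat(X, epochs$fs)
    ops <- dwt_operators(n)
    wl <- do.call(cbind, lapply(WL_SETS, function(s) {
      C <- ops[[s]] %*% X
      st <- epoch_stats(C, full = FALSE)
      colnames(st) <- paste(s, WL_MEASURES, sep = "_")
      st
    }))
    blk <- cbind(td, bp, wl)
    colnames(blk) <- paste(ch, colnames(blk), sep = ".")
    blk
  })
  corr <- do.call(cbind, lapply(CORR_PAIRS, function(p) {
    col_corr(matrix(arr[, p[1], ], nrow = n), matrix(arr[, p[2], ], nrow = n))
  }))
  colnames(corr) <- vapply(CORR_PAIRS, function(p) paste0("corr.", p[1], "__", p[2]), "")
  tab <- cbind(do.call(cbind, blocks), corr)
  tab <- tab[, feature_columns(), drop = FALSE]
  tibble::as_tibble(cbind(tibble::tibble(epoch = seq_len(m) - 1),
                          tibble::as_tibble(tab)))
}

#' Band-pass, epoch, and extract features of one recording
#'
#' Convenience pipeline stage: [eeg_bandpass()] then [eeg_epoch()] then
#' [extract_feature_table()], tagging rows with the recording id.
#'
#' @param rec An [eeg_recording()] (already windowed to the postictal
#'   analysis period).
#' @param low,high Band-pass edges in Hz.
#' @return A tibble: `recording_id`, `epoch`, then the 612 features.
#' @export
pges_features <- function(rec, low = 0.5, high = 5) {
  ft <- extract_feature_table(eeg_epoch(eeg_bandpass(rec, low, high)))
  dplyr::bind_cols(tibble::tibble(recording_id = rep(rec$id, nrow(ft))), ft)
}

#' Feature tables for a list of recordings
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param low,high Band-pass edges in Hz.
#' @return A stacked tibble of [pges_features()] results.
#' @export
pges_features_dataset <- function(recordings, low = 0.5, high = 5) {
  purrr::map_dfr(recordings, pges_features, low = low, high = high)
}
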