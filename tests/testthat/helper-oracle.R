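# Independent brute-force feature oracle: every quantity evaluated straight
# from its definition with base R, sharing no code with the package
# internals (which use composed matrix operators and vectorized moments).

bf_popvar <- function(x) mean((x - mean(x))^2)

bf_stats <- function(x, full = TRUE) {
  m2 <- bf_popvar(x)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  d <- diff(x)
  dd <- diff(d)
  mob <- if (m2 > 0) sqrt(bf_popvar(d) / m2) else 0
  mob_d <- if (bf_popvar(d) > 0) sqrt(bf_popvar(dd) / bf_popvar(d)) else 0
  out <- c(
    mean = mean(x), median = unname(quantile(x, 0.5, type = 7)),
    max = max(x), min = min(x), range = max(x) - min(x), std = sqrt(m2),
    p05 = unname(quantile(x, 0.05, type = 7)),
    p25 = unname(quantile(x, 0.25, type = 7)),
    p75 = unname(quantile(x, 0.75, type = 7)),
    p95 = unname(quantile(x, 0.95, type = 7)),
    rms = sqrt(mean(x^2)),
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    mobility = mob,
    complexity = if (mob > 0) mob_d / mob else 0,
    ae = sum(x^2)
  )
  if (!full) out <- out[setdiff(names(out), c("range", "ae"))]
  out
}

bf_band_power <- function(x, fs, lo, hi, closed_hi) {
  n <- length(x)
  npad <- 8 * n
  X <- fft(c(x, rep(0, npad - n)))
  k <- 1:(npad %/% 2 - 1)           # positive frequencies, no DC/Nyquist
  f <- k * fs / npad
  sel <- k[f >= lo & (if (closed_hi) f <= hi else f < hi)]
  sum(2 * Mod(X[sel + 1])^2 / (npad * n))
}

BF_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
               0.030841381835560764, -0.18703481171909309,
               -0.027983769416859854, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965)
BF_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
               -0.6308807679298589, -0.027983769416859854,
               0.18703481171909309, 0.030841381835560764,
               -0.0328830116668852, -0.010597401785069032)

# decimated convolution straight from the definition, one output at a time
bf_dwt_step <- function(x, f) {
  L <- length(f); n <- length(x)
  ext <- c(rev(x[1:(L - 1)]), x, rev(x[(n - L + 2):n]))
  vapply(0:((n + L - 1) %/% 2 - 1), function(k) {
    i <- L + 2 * k
    s <- 0
    for (j in (i - L + 1):i) s <- s + ext[j + 1] * f[i - j + 1]
    s
  }, numeric(1))
}

bf_dwt3 <- function(x) {
  a1 <- bf_dwt_step(x, BF_DEC_LO); d1 <- bf_dwt_step(x, BF_DEC_HI)
  a2 <- bf_dwt_step(a1, BF_DEC_LO); d2 <- bf_dwt_step(a1, BF_DEC_HI)
  a3 <- bf_dwt_step(a2, BF_DEC_LO); d3 <- bf_dwt_step(a2, BF_DEC_HI)
  list(cA3 = a3, cD3 = d3, cD2 = d2, cD1 = d1)
}

# all 612 features of one 8-channel epoch, as a named vector
bf_epoch_features <- function(epoch, fs) {
  chans <- colnames(epoch)
  out <- c()
  for (ch in chans) {
    x <- epoch[, ch]
    td <- bf_stats(x)
    bp <- c(bf_band_power(x, fs, 0.5, 1, FALSE),
            bf_band_power(x, fs, 1, 2, FALSE),
            bf_band_power(x, fs, 2, 4, FALSE),
            bf_band_power(x, fs, 4, 5, TRUE))
    names(bp) <- c("bp_0.5_1", "bp_1_2", "bp_2_4", "bp_4_5")
    cf <- bf_dwt3(x)
    wl <- unlist(lapply(names(cf), function(s) {
      v <- bf_stats(cf[[s]], full = FALSE)
      names(v) <- paste(s, names(v), sep = "_")
      v
    }))
    blk <- c(td, bp, wl)
    names(blk) <- paste(ch, names(blk), sep = ".")
    out <- c(out, blk)
  }
  pairs <- list(c("Fp1-F7", "Fp2-F8"), c("Fp2-F8", "Fz-Cz"),
                c("Fp1-F7", "Fz-Cz"), c("Fz-Cz", "Cz-Pz"))
  cr <- vapply(pairs, function(p) {
    a <- epoch[, p[1]]; b <- epoch[, p[2]]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }, numeric(1))
  names(cr) <- vapply(pairs, function(p) paste0("corr.", p[1], "__", p[2]), "")
  c(out, cr)
}

# compare package feature rows against the oracle on random epochs
compare_features_to_oracle <- function(n_epochs, fs = 256, seed = 42,
                                       tol = 1e-9) {
  set.seed(seed)
  arr <- array(rnorm(fs * 8 * n_epochs, sd = 20), dim = c(fs, 8, n_epochs),
               dimnames = list(NULL, pges_channels(), NULL))
  ep <- structure(list(epochs = arr, fs = fs, channels = pges_channels(),
                       n_epochs = n_epochs, epoch_seconds = 1, origin = 0,
                       annotation = NA_real_, id = "oracle",
                       artifact_level = NA_character_),
                  class = "eeg_epochs")
  ft <- extract_feature_table(ep)
  worst_rel <- 0; worst_abs <- 0
  for (e in seq_len(n_epochs)) {
    ref <- bf_epoch_features(arr[, , e], fs)
    got <- unlist(ft[e, names(ref)])
    big <- abs(ref) > 1e-6        # relative error where it is meaningful
    if (any(big)) {
      worst_rel <- max(worst_rel, max(abs(got[big] - ref[big]) / abs(ref[big])))
    }
    if (any(!big)) {
      worst_abs <- max(worst_abs, max(abs(got[!big] - ref[!big])))
    }
  }
  list(rel = worst_rel, abs = worst_abs)
}
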