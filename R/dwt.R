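# Daubechies-4 discrete wavelet transform, three-level, with symmetric
# (half-sample) boundary extension. Implemented directly so the boundary
# convention is fixed and documented; validated in the tests against
# reference coefficient vectors. The decimated transform is linear, so for
# feature extraction over many epochs the per-level analysis operators are
# composed once into dense matrices and applied to all epochs of a channel
# in a single matrix product.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- c(0.2303778133088965, 0.7148465705529157,
                0.6308807679298589, -0.027983769416859854,
                -0.18703481171909309, 0.030841381835560764,
                0.0328830116668852, -0.010597401785069032)
DB4_REC_HI <- c(-0.010597401785069032, -0.0328830116668852,
                0.030841381835560764, 0.18703481171909309,
                -0.027983769416859854, -0.6308807679298589,
                0.7148465705529157, -0.2303778133088965)

dwt_out_len <- function(n) (n + 7L) %/% 2L

# analysis operator for one level as a dense matrix: symmetric extension by
# L-1 samples, full convolution with the filter, downsample keeping full-conv
# indices L, L+2, ... (0-based)
dwt_level_matrix <- function(n, f) {
  L <- length(f)
  map <- c((L - 1):1, 1:n, n:(n - L + 2))       # extension -> sample index
  out_len <- dwt_out_len(n)
  M <- matrix(0, out_len, n)
  for (k in 0:(out_len - 1)) {
    i <- L + 2 * k                               # full-conv index, 0-based
    js <- (i - L + 1):i                          # extension indices, 0-based
    js <- js[js >= 0 & js < length(map)]
    for (j in js) {
      M[k + 1, map[j + 1]] <- M[k + 1, map[j + 1]] + f[i - j + 1]
    }
  }
  M
}

.dwt_cache <- new.env(parent = emptyenv())

# composed analysis operators for a 3-level decomposition of length-n signals:
# matrices mapping the signal directly to cA3, cD3, cD2, cD1
dwt_operators <- function(n) {
  key <- as.character(n)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  n1 <- dwt_out_len(n); n2 <- dwt_out_len(n1); n3 <- dwt_out_len(n2)
  A1 <- dwt_level_matrix(n, DB4_DEC_LO);  D1 <- dwt_level_matrix(n, DB4_DEC_HI)
  A2 <- dwt_level_matrix(n1, DB4_DEC_LO); D2 <- dwt_level_matrix(n1, DB4_DEC_HI)
  A3 <- dwt_level_matrix(n2, DB4_DEC_LO); D3 <- dwt_level_matrix(n2, DB4_DEC_HI)
  ops <- list(
    cA3 = A3 %*% A2 %*% A1,
    cD3 = D3 %*% A2 %*% A1,
    cD2 = D2 %*% A1,
    cD1 = D1,
    lengths = c(n = n, n1 = n1, n2 = n2, n3 = n3)
  )
  .dwt_cache[[key]] <- ops
  ops
}

#' Three-level db4 wavelet decomposition
#'
#' Decomposes a signal with the 8-tap Daubechies-4 wavelet to three levels
#' under symmetric (half-sample) boundary extension, yielding the
#' approximation set `cA3` and detail sets `cD3`, `cD2`, `cD1`. For 0.5-5 Hz
#' EEG epochs the detail sets isolate successively slower dyadic bands.
#'
#' @param x Numeric vector, length >= 32.
#' @return Named list `cA3`, `cD3`, `cD2`, `cD1` with an attribute
#'   `lengths` recording the per-level signal lengths (used by
#'   [idwt_db4()]).
#' @export
dwt_db4 <- function(x) {
  n <- length(x)
  if (n < 32) {
    abort("db4 three-level decomposition needs at least 32 samples.",
          class = "pges_parameter_error")
  }
  ops <- dwt_operators(n)
  out <- list(cA3 = drop(ops$cA3 %*% x), cD3 = drop(ops$cD3 %*% x),
              cD2 = drop(ops$cD2 %*% x), cD1 = drop(ops$cD1 %*% x))
  attr(out, "lengths") <- ops$lengths
  out
}

# one synthesis step: upsample, convolve with reconstruction filters, trim
idwt_step <- function(a, d, out_len) {
  L <- 8
  up <- function(c) { u <- numeric(2 * length(c)); u[seq(1, by = 2, length.out = length(c))] <- c; u }
  s <- convolve(up(a), rev(DB4_REC_LO), type = "open") +
       convolve(up(d), rev(DB4_REC_HI), type = "open")
  s[(L - 1):(L - 2 + out_len)]
}

#' Inverse three-level db4 wavelet transform
#'
#' Reconstructs the signal from the four coefficient sets produced by
#' [dwt_db4()]. Reconstruction is exact to numerical precision.
#'
#' @param coeffs Output of [dwt_db4()].
#' @return Numeric vector of the original length.
#' @export
idwt_db4 <- function(coeffs) {
  lens <- attr(coeffs, "lengths")
  if (is.null(lens)) {
    abort("`coeffs` must come from dwt_db4() (missing lengths attribute).",
          class = "pges_parameter_error")
  }
  a <- idwt_step(coeffs$cA3, coeffs$cD3, lens[["n2"]])
  a <- idwt_step(a, coeffs$cD2, lens[["n1"]])
  idwt_step(a, coeffs$cD1, lens[["n"]])
}
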