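# Reference coefficients computed once with PyWavelets (pywt 1.9, 'db4',
# mode='symmetric', level=3) for x = sin(2*pi*3*t/32) + 0.5*cos(2*pi*t/32),
# t = 0..31, and frozen here.
PYWT_X <- sin(2 * pi * 3 * (0:31) / 32) + 0.5 * cos(2 * pi * (0:31) / 32)
PYWT_CA3 <- c(2.769003411157543, 2.9219713733067625, 3.0084497406518027,
              2.743702383652231, 3.6645716350642874, 0.44256709356630614,
              -1.383756689864377, 0.10035060396735207, -0.36711899193572417,
              -1.0228057662695784)
PYWT_CD3 <- c(0.1388075832850467, 0.5019006878769392, 0.9297355032434858,
              -1.1491257621830049, -2.2142663597125667, 1.336798270749821,
              -0.3030789016190322, -0.06527793547164054, -0.5840681329810159,
              2.826954328792408)
PYWT_CD2_HEAD <- c(-0.2630237032061458, -0.8017193446336347,
                   0.6214103774736925, -0.6854932159928666)
PYWT_CD1_HEAD <- c(0.03412438694614485, 0.06045813354555299,
                   -0.08702267019868429, -0.03146400551957157)

test_that("db4 decomposition matches the frozen reference coefficients", {
  cf <- dwt_db4(PYWT_X)
  expect_equal(cf$cA3, PYWT_CA3, tolerance = 1e-12)
  expect_equal(cf$cD3, PYWT_CD3, tolerance = 1e-12)
  expect_equal(cf$cD2[1:4], PYWT_CD2_HEAD, tolerance = 1e-12)
  expect_equal(cf$cD1[1:4], PYWT_CD1_HEAD, tolerance = 1e-12)
  expect_equal(lengths(cf[c("cA3", "cD3", "cD2", "cD1")]),
               c(cA3 = 10L, cD3 = 10L, cD2 = 13L, cD1 = 19L))
})

test_that("inverse DWT reconstructs random signals to 1e-8 relative error", {
  set.seed(7)
  for (n in c(32, 64, 256)) {
    x <- rnorm(n)
    xr <- idwt_db4(dwt_db4(x))
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  }
})

test_that("DWT of a constant signal concentrates in the approximation set", {
  cf <- dwt_db4(rep(3, 64))
  expect_lt(max(abs(cf$cD1)), 1e-12)
  expect_lt(max(abs(cf$cD2)), 1e-12)
  expect_lt(max(abs(cf$cD3)), 1e-12)
  expect_equal(mean(cf$cA3), 3 * 2^(3 / 2), tolerance = 1e-12)  # gain sqrt(2)/level
})

test_that("time-domain features handle constant and symmetric signals", {
  td <- time_domain_features(c(1, 1, 1, 1))
  expect_equal(unname(td[c("mean", "range", "std", "rms", "ae",
                           "mobility", "complexity",
                           "skewness", "kurtosis")]),
               c(1, 0, 0, 1, 4, 0, 0, 0, 0))
  td2 <- time_domain_features(c(-1, 1, -1, 1))
  expect_equal(unname(td2[c("mean", "range", "rms", "ae")]), c(0, 2, 1, 4))
  expect_error(time_domain_features(c(1, 2, 3)), class = "pges_parameter_error")
})

test_that("Hjorth mobility of a sampled sinusoid matches 2*sin(pi*f/fs)", {
  fs <- 256
  x <- sin(2 * pi * 2 * (0:(fs - 1)) / fs)
  td <- time_domain_features(x)
  expect_equal(unname(td["mobility"]), 2 * sin(pi * 2 / fs), tolerance = 0.01)
})

test_that("band powers localize a pure tone and vanish on silence", {
  expect_equal(unname(band_powers(rep(0, 256), 256)), rep(0, 4))
  bp <- band_powers(sin(2 * pi * 3 * (0:255) / 256), 256)
  expect_gt(bp[["bp_2_4"]] / sum(bp), 0.9)
  expect_error(band_powers(rnorm(8), 8), class = "pges_parameter_error")
})

test_that("four-band power never exceeds total signal power (Parseval)", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(256)
    expect_lte(sum(band_powers(x, 256)), mean(x^2) + 1e-12)
  }
})

test_that("wavelet features of silence are all zero", {
  wf <- wavelet_features(rep(0, 64))
  expect_equal(length(wf), 56)
  expect_equal(unname(wf), rep(0, 56))
})

test_that("interchannel correlations obey sign and degeneracy conventions", {
  n <- 256
  x <- sin(2 * pi * 2 * (0:(n - 1)) / n)
  ep <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, pges_channels()))
  ep[, "Fp1-F7"] <- x
  ep[, "Fp2-F8"] <- x
  ep[, "Fz-Cz"] <- -x
  ep[, "Cz-Pz"] <- 0   # constant channel
  cc <- interchannel_correlations(ep)
  expect_equal(unname(cc["corr.Fp1-F7__Fp2-F8"]), 1)
  expect_equal(unname(cc["corr.Fp1-F7__Fz-Cz"]), -1)
  expect_equal(unname(cc["corr.Fz-Cz__Cz-Pz"]), 0)  # zero-variance convention
  expect_error(interchannel_correlations(ep[, 1:3]),
               class = "pges_channel_error")
})

test_that("independent noise channels correlate weakly", {
  set.seed(11)
  for (i in 1:50) {
    ep <- matrix(rnorm(256 * 8), 256, 8,
                 dimnames = list(NULL, pges_channels()))
    expect_lt(max(abs(interchannel_correlations(ep))), 0.3)
  }
})

test_that("feature tables have the documented shape and order", {
  cols <- feature_columns()
  expect_length(cols, 612)
  expect_equal(sum(startsWith(cols, "corr.")), 4)
  rec <- eeg_recording(matrix(rnorm(256 * 5 * 8), ncol = 8), fs = 256)
  ft <- extract_feature_table(eeg_epoch(rec))
  expect_equal(dim(ft), c(5, 613))
  expect_identical(setdiff(names(ft), "epoch"), cols)
  expect_false(anyNA(ft))
})

test_that("identical epochs give identical rows; channel order is immaterial", {
  set.seed(5)
  block <- matrix(rnorm(256 * 8), ncol = 8)
  rec <- eeg_recording(rbind(block, block), fs = 256)
  ft <- extract_feature_table(eeg_epoch(rec))
  expect_equal(unlist(ft[1, -1]), unlist(ft[2, -1]))

  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  rec_p <- eeg_recording(block[, perm], fs = 256,
                         channels = pges_channels()[perm])
  ft_p <- extract_feature_table(eeg_epoch(rec_p))
  expect_equal(unlist(ft_p[1, -1]), unlist(ft[1, -1]))
})

test_that("features obey shift and scale covariances", {
  set.seed(9)
  x <- rnorm(256)
  a <- time_domain_features(x)
  b <- time_domain_features(x + 10)
  expect_equal(b[c("std", "mobility", "complexity", "skewness", "kurtosis")],
               a[c("std", "mobility", "complexity", "skewness", "kurtosis")])
  expect_equal(unname(b["mean"]), unname(a["mean"]) + 10)
  k <- -2.5
  s <- time_domain_features(k * x)
  expect_equal(unname(s[c("std", "range", "rms")]),
               abs(k) * unname(a[c("std", "range", "rms")]))
  expect_equal(unname(s["ae"]), k^2 * unname(a["ae"]))
  expect_equal(s[c("mobility", "complexity", "kurtosis")],
               a[c("mobility", "complexity", "kurtosis")])
})

test_that("all 612 features match the brute-force oracle on random epochs", {
  err <- compare_features_to_oracle(10, fs = 64, seed = 21)
  expect_lt(err$rel, 1e-9)
  expect_lt(err$abs, 1e-12)
})
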