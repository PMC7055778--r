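test_that("bipolar montage is derived from referential channels by subtraction", {
  vals <- c(Fp1 = 10, F7 = 4, T7 = 1, P7 = 0.5, Fp2 = 8, F8 = 3,
            T8 = 2, P8 = 1, Fz = 6, Cz = 2, Pz = -1)
  rec <- fx_referential_recording(vals)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  got <- read_edf(path)
  expect_equal(got$channels, pges_channels())
  # Fp1-F7 = 10 - 4 = 6, constant
  expect_equal(unname(got$data[1, "Fp1-F7"]), 6, tolerance = 1e-3)
  expect_equal(unname(got$data[10, "Fz-Cz"]), 4, tolerance = 1e-3)
  expect_lt(max(abs(got$data[, "Fp1-F7"] - 6)), 1e-3)
})

test_that("EDF label matching tolerates case and common prefixes/suffixes", {
  vals <- c(10, 4, 1, 0.5, 8, 3, 2, 1, 6, 2, -1)
  labels <- c("EEG Fp1-REF", "f7", "EEG T7-REF", "p7-REF", "FP2", "F8-ref",
              "EEG t8", "P8", "EEG FZ-REF", "cz", "Pz-REF")
  rec <- fx_referential_recording(vals, labels = labels)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  got <- read_edf(path)
  expect_equal(unname(got$data[1, "Fp1-F7"]), 6, tolerance = 1e-3)
  expect_equal(unname(got$data[1, "T8-P8"]), 1, tolerance = 1e-3)
})

test_that("a file already in bipolar montage is read directly", {
  sp <- synthetic_spec(duration = 30, pges_duration = 10, seed = 2)
  rec <- generate_recording(sp)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  got <- read_edf(path, annotation = 10)
  expect_equal(got$channels, pges_channels())
  expect_equal(got$annotation, 10)
})

test_that("EDF round trip recovers samples within 16-bit quantization", {
  sp <- synthetic_spec(duration = 20, pges_duration = 8, seed = 11,
                       artifact_level = "severe")
  rec <- generate_recording(sp)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  got <- read_edf(path)
  step <- (2 * max(pmax(apply(abs(rec$data), 2, max) * 1.02, 1))) / 65535
  expect_lt(max(abs(got$data - rec$data)), step)
})

test_that("missing electrodes produce a channel error naming them", {
  vals <- c(10, 4, 1, 0.5, 8, 3, 6, 2, -1)
  labels <- c("Fp1", "F7", "T7", "P7", "Fp2", "F8", "Fz", "Cz", "Pz")  # no T8, P8
  rec <- fx_referential_recording(vals, labels = labels)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_edf(path), class = "pges_channel_error", regexp = "T8")
})

test_that("unreadable files raise a format error", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", path)
  expect_error(read_edf(path), class = "pges_format_error")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")),
               class = "pges_format_error")
})

test_that("montage derivation is linear in the referential inputs", {
  vals <- c(10, 4, 1, 0.5, 8, 3, 2, 1, 6, 2, -1)
  p1 <- withr::local_tempfile(fileext = ".edf")
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(fx_referential_recording(vals), p1)
  write_edf(fx_referential_recording(3 * vals), p2)
  a <- read_edf(p1); b <- read_edf(p2)
  expect_equal(b$data[1, ], 3 * a$data[1, ], tolerance = 1e-2)
})

test_that("resampling maps a series onto a higher rate preserving shape", {
  x <- sin(2 * pi * 2 * seq(0, 4 - 1 / 64, by = 1 / 64))
  y <- pgesr:::edf_resample(x, 64, 256)
  expect_equal(length(y), 4 * 256)
  t_new <- (seq_along(y) - 1) / 256
  interior <- t_new <= 3.9   # beyond the last source sample it extrapolates
  expect_lt(max(abs(y[interior] - sin(2 * pi * 2 * t_new[interior]))), 0.01)
})

test_that("postictal window extraction shifts the origin and annotations", {
  fs <- 64
  rec <- eeg_recording(matrix(rnorm(600 * fs * 8), ncol = 8), fs = fs,
                       t0 = 0, annotation = 130)
  win <- extract_postictal_window(rec, t0 = 100, duration = 300)
  expect_equal(recording_duration(win), 300)
  expect_equal(win$t0, 0)
  expect_equal(win$annotation, 30)   # absolute 130 s -> 30 s after window start
  expect_equal(win$data[1, ], rec$data[100 * fs + 1, ])
})

test_that("window extraction errors when the window exceeds the file", {
  rec <- eeg_recording(matrix(0, 200 * 64, 8), fs = 64)
  expect_error(extract_postictal_window(rec, t0 = 0, duration = 300),
               class = "pges_bounds_error")
  expect_error(extract_postictal_window(rec, t0 = 0, duration = 0),
               class = "pges_parameter_error")
})

test_that("a full-length window is the identity on samples", {
  rec <- eeg_recording(matrix(rnorm(50 * 64 * 8), ncol = 8), fs = 64)
  win <- extract_postictal_window(rec, t0 = 0, duration = 50)
  expect_identical(win$data, rec$data)
})

test_that("annotation sidecars are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    recording_id = "r1", t0_seconds = 0, isw_onset_seconds = 30,
    artifact_level = "free"), path)
  ann <- read_annotations(path)
  expect_named(ann, c("recording_id", "t0_seconds", "isw_onset_seconds",
                      "artifact_level"))
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(recording_id = "r1", t0_seconds = 0), bad)
  expect_error(read_annotations(bad), class = "pges_format_error")
})
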