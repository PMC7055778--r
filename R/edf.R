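# Minimal EDF (European Data Format) support: 16-bit samples, header-driven
# physical scaling, 1-second data records. Covers what the pipeline needs --
# reading referential or bipolar scalp montages and writing the synthetic
# generator's output -- not the full EDF+ annotation machinery.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range chosen
#' per channel from the data, so the round-trip error is bounded by half a
#' quantization step. Only whole 1-second data records are written; a
#' trailing partial second is dropped.
#'
#' @param rec An [eeg_recording()] (units: microvolts; integer `fs`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) {
    abort("EDF writing requires an integer sampling rate.",
          class = "pges_parameter_error")
  }
  n_rec <- floor(nrow(rec$data) / fs)
  if (n_rec < 1) abort("Recording shorter than one EDF data record.",
                       class = "pges_parameter_error")
  data <- rec$data[seq_len(n_rec * fs), , drop = FALSE]
  ns <- ncol(data)

  phys_max <- pmax(apply(abs(data), 2, max) * 1.02, 1)
  phys_min <- -phys_max
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(ifelse(is.na(rec$id), "X", rec$id), 80),
    edf_pad("Startdate 01-JAN-2000", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(vapply(phys_min, edf_num, ""), 8)
  field(vapply(phys_max, edf_num, ""), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)

  # header strings were formatted with 7 significant digits; requantize
  # against the values a reader will parse back
  pm <- as.numeric(vapply(phys_max, edf_num, ""))
  pmin <- as.numeric(vapply(phys_min, edf_num, ""))
  scale <- (pm - pmin) / (dig_max - dig_min)
  dig <- matrix(0L, nrow(data), ns)
  for (j in seq_len(ns)) {
    d <- round((data[, j] - pmin[j]) / scale[j]) + dig_min
    dig[, j] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  # interleave by record: record r = fs samples of ch1, fs of ch2, ...
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  out <- integer(n_rec * fs * ns)
  pos <- 1L
  for (r in seq_len(n_rec)) {
    block <- dig[idx[, r], , drop = FALSE]
    out[pos:(pos + fs * ns - 1L)] <- as.integer(block)
    pos <- pos + fs * ns
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

edf_clean_label <- function(x) {
  x <- toupper(gsub("\\s+", "", x))
  x <- sub("^EEG", "", x)
  x
}

# strip a reference suffix ("FP1-REF" -> "FP1"); bipolar labels keep both sides
edf_electrode_of <- function(clean) {
  sub("-(REF|LE|AVG|AV|A1|A2|M1|M2|G2)$", "", clean)
}

edf_read_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) {
    abort("Not an EDF file (bad version field).", class = "pges_format_error")
  }
  patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16); transducer <- fields(80); dim <- fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  prefilter <- fields(80); spr <- as.integer(fields(8)); fields(32)
  list(patient = patient, recording = recording, n_rec = n_rec,
       rec_dur = rec_dur, ns = ns, labels = labels, dim = dim,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF recording and derive the bipolar montage
#'
#' Reads an EDF/EDF+ file and returns the 8-channel bipolar recording the
#' pipeline operates on. Files already stored in the bipolar montage are used
#' directly; referential montages (e.g. `EEG Fp1-REF`) are converted by
#' subtraction (`Fp1-F7 = Fp1 - F7`). Label matching is case-insensitive and
#' ignores an `EEG` prefix, whitespace, and common reference suffixes.
#' Channels stored at different sampling rates are linearly resampled to the
#' highest rate among the channels used. Physical units are normalized to
#' microvolts from the header dimension field (`uV`, `mV`, or `V`).
#'
#' @param path Path to an EDF file.
#' @param t0 Seizure-end time in seconds from file start (analysis origin).
#' @param annotation Optional first-ISW onset in seconds after `t0`.
#' @param id Recording identifier; defaults to the file name.
#' @param artifact_level Optional artifact grade.
#' @return An [eeg_recording()] with the canonical 8 channels.
#' @export
read_edf <- function(path, t0 = 0, annotation = NA_real_,
                     id = sub("\\.edf$", "", basename(path), ignore.case = TRUE),
                     artifact_level = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("EDF file not found: %s", path), class = "pges_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(edf_read_header(con), error = function(e) {
    abort(sprintf("Unreadable EDF header in %s: %s", path, conditionMessage(e)),
          class = "pges_format_error")
  })
  total <- h$n_rec * sum(h$spr)
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little")
  if (length(raw) < total) {
    abort(sprintf("Truncated EDF data in %s", path), class = "pges_format_error")
  }
  # de-interleave records
  sig <- vector("list", h$ns)
  offs <- c(0, cumsum(h$spr))
  rec_len <- sum(h$spr)
  for (j in seq_len(h$ns)) {
    pick <- outer(seq_len(h$spr[j]) + offs[j], (seq_len(h$n_rec) - 1) * rec_len, "+")
    dig <- raw[as.vector(pick)]
    scale <- (h$pmax[j] - h$pmin[j]) / (h$dmax[j] - h$dmin[j])
    phys <- (dig - h$dmin[j]) * scale + h$pmin[j]
    unit <- toupper(h$dim[j])
    if (unit == "MV") phys <- phys * 1e3
    if (unit == "V") phys <- phys * 1e6
    sig[[j]] <- phys
  }
  fs_sig <- h$spr / h$rec_dur
  clean <- edf_clean_label(h$labels)
  keep <- clean != "EDFANNOTATIONS"

  want <- pges_channels()
  want_clean <- toupper(want)
  # direct bipolar match
  direct <- match(want_clean, clean)
  if (all(!is.na(direct))) {
    cols <- as.list(direct)
    fs_used <- fs_sig[direct]
    get_series <- function(k) sig[[cols[[k]]]]
  } else {
    electrodes <- edf_electrode_of(clean)
    electrodes[!keep] <- ""
    pairs <- strsplit(want_clean, "-", fixed = TRUE)
    need <- unique(unlist(pairs))
    found <- match(need, electrodes)
    if (anyNA(found)) {
      missing <- need[is.na(found)]
      abort(sprintf("EDF is missing required electrode(s): %s",
                    paste(missing, collapse = ", ")),
            class = "pges_channel_error")
    }
    names(found) <- need
    fs_used <- fs_sig[found[unique(unlist(pairs))]]
    get_series <- function(k) {
      a <- sig[[found[pairs[[k]][1]]]]
      b <- sig[[found[pairs[[k]][2]]]]
      fa <- fs_sig[found[pairs[[k]][1]]]
      fb <- fs_sig[found[pairs[[k]][2]]]
      fmax <- max(fs_used)
      a <- edf_resample(a, fa, fmax)
      b <- edf_resample(b, fb, fmax)
      n <- min(length(a), length(b))
      a[seq_len(n)] - b[seq_len(n)]
    }
  }
  fs <- max(fs_used)
  series <- lapply(seq_along(want), function(k) {
    edf_resample(get_series(k), if (exists("direct") && all(!is.na(direct)))
      fs_sig[direct[k]] else fs, fs)
  })
  n <- min(lengths(series))
  data <- vapply(series, function(s) s[seq_len(n)], numeric(n))
  eeg_recording(data, fs = fs, channels = want, t0 = t0,
                annotation = annotation, id = id,
                artifact_level = artifact_level)
}

edf_resample <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  dur <- length(x) / fs_from
  t_new <- seq(0, dur - 1 / fs_to, by = 1 / fs_to)
  approx(x = (seq_along(x) - 1) / fs_from, y = x, xout = t_new, rule = 2)$y
}

#' Read an annotation sidecar CSV
#'
#' The sidecar accompanies a directory of EDF files and carries, per
#' recording: the seizure-end time `t0_seconds` (analysis origin), the
#' expert first-ISW onset `isw_onset_seconds` (relative to t0), and the
#' artifact grade.
#'
#' @param path CSV with columns `recording_id`, `t0_seconds`,
#'   `isw_onset_seconds`, `artifact_level`.
#' @return A tibble with those columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("recording_id", "t0_seconds", "isw_onset_seconds", "artifact_level")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    abort(sprintf("Annotation file lacks column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "pges_format_error")
  }
  bad <- setdiff(unique(ann$artifact_level), c("free", "mild", "moderate", "severe"))
  if (length(bad)) {
    abort(sprintf("Unknown artifact level(s): %s", paste(bad, collapse = ", ")),
          class = "pges_format_error")
  }
  tibble::as_tibble(ann[need])
}
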