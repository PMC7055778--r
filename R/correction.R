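# Confidence-based temporal correction. Sudden PGES -> ISW -> PGES flips are
# physiologically implausible (suppression rarely resumes once slow waves
# appear), so isolated ISW detections with unsupportive temporal context are
# relabeled as PGES. Corrections are one-directional: no rule ever turns a
# PGES label into ISW, hence the detected onset can only move later.

#' Confidence index of a probability sequence
#'
#' `conf_i` is the mean of `P(ISW)` from the current epoch through the next
#' `M` epochs (`M + 1` terms), truncated at the end of the sequence; the
#' final epoch's confidence is its own probability. A forward-looking moving
#' average: high only when slow-wave evidence is sustained.
#'
#' @param probs Numeric vector of per-epoch `P(ISW)`.
#' @param M Number of look-ahead epochs (default 5).
#' @return Numeric vector of the same length, values in `[0, 1]`.
#' @export
confidence_index <- function(probs, M = 5) {
  n <- length(probs)
  if (n < 1) abort("Empty probability sequence.", class = "pges_parameter_error")
  if (M < 0) abort("`M` must be >= 0.", class = "pges_parameter_error")
  cs <- cumsum(probs)
  hi <- pmin(seq_len(n) + M, n)
  (cs[hi] - c(0, cs[-n])) / (hi - seq_len(n) + 1)
}

#' Apply the three confidence-based correction rules
#'
#' A single pass over a frozen copy of the inputs; each epoch currently
#' labeled ISW is relabeled PGES if any rule fires:
#' \describe{
#'   \item{Rule 1}{its probability is high (`>= hi`) but both neighbors'
#'     probabilities are low (`< lo`) -- an isolated probability spike;}
#'   \item{Rule 2}{its confidence is high but both neighbors' confidences
#'     are low -- an isolated confidence spike;}
#'   \item{Rule 3}{its probability is high but its own confidence is low --
#'     a spike with no sustained follow-up.}
#' }
#' At the sequence boundaries the comparison against a missing neighbor is
#' skipped (treated as satisfied). Labels change only from ISW to PGES.
#'
#' @param labels Integer 0/1 label vector.
#' @param probs Per-epoch `P(ISW)` (same length).
#' @param conf Confidence index from [confidence_index()] (same length).
#' @param hi Threshold at or above which a value counts as "high".
#' @param lo Threshold below which a value counts as "low"; `hi >= lo`.
#' @return Corrected integer label vector.
#' @export
apply_correction_rules <- function(labels, probs, conf = confidence_index(probs),
                                   hi = 0.5, lo = 0.5) {
  n <- length(labels)
  if (length(probs) != n || length(conf) != n) {
    abort("`labels`, `probs` and `conf` must have equal length.",
          class = "pges_alignment_error")
  }
  if (hi < lo) abort("`hi` must be >= `lo`.", class = "pges_parameter_error")
  prev_lo <- function(x) c(TRUE, x[-n] < lo)       # missing neighbor satisfied
  next_lo <- function(x) c(x[-1] < lo, TRUE)
  r1 <- probs >= hi & prev_lo(probs) & next_lo(probs)
  r2 <- conf >= hi & prev_lo(conf) & next_lo(conf)
  r3 <- probs >= hi & conf < lo
  out <- labels
  out[labels == 1L & (r1 | r2 | r3)] <- 0L
  out
}

#' First-ISW onset of a label sequence
#'
#' @param labels Integer 0/1 label vector (epoch 0 = first postictal second).
#' @return Onset in whole seconds after t0 (the index of the first ISW
#'   epoch), or `NA` if no epoch is labeled ISW.
#' @export
detect_first_isw_onset <- function(labels) {
  i <- which(labels == 1L)
  if (length(i) == 0) return(NA_real_)
  as.numeric(i[1] - 1)
}

#' Detect the PGES end of one feature table
#'
#' Full read-out chain for a single recording: classifier probabilities,
#' thresholding, confidence index, correction rules, first-ISW onset.
#'
#' @param model A [pges_rf()] model.
#' @param features Feature tibble of one recording (one row per epoch, in
#'   epoch order).
#' @param threshold Classification threshold.
#' @param M Confidence look-ahead (epochs).
#' @param hi,lo Correction-rule thresholds.
#' @return One-row tibble: `predicted_onset` (s, `NA` if none), `n_epochs`,
#'   plus list columns `probs`, `labels_raw`, `labels` with the per-epoch
#'   sequences.
#' @export
detect_pges_end <- function(model, features, threshold = 0.5, M = 5,
                            hi = 0.5, lo = 0.5) {
  probs <- predict_proba(model, features)
  raw <- predict_labels(probs, threshold)
  conf <- confidence_index(probs, M)
  lab <- apply_correction_rules(raw, probs, conf, hi, lo)
  tibble::tibble(
    predicted_onset = detect_first_isw_onset(lab),
    n_epochs = length(lab),
    probs = list(probs), labels_raw = list(raw), labels = list(lab)
  )
}
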