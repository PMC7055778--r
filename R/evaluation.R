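# Recording-level evaluation: what matters clinically is how far the
# detected PGES end lies from the expert's, not how many individual epochs
# are classified correctly. A detector can score 29/30 epochs yet be 15 s
# off -- hence the time-distance metrics, with the traditional
# segment-based metrics kept for comparison.

#' Predicted time distance
#'
#' Absolute difference in seconds between the predicted and the annotated
#' first-ISW onset. A recording with no prediction gets `NA`, which counts
#' as outside every tolerance.
#'
#' @param predicted Predicted onset(s) in seconds, `NA` for no detection.
#' @param annotated Annotated onset(s) in seconds.
#' @return Numeric vector of absolute time distances.
#' @export
predicted_time_distance <- function(predicted, annotated) {
  abs(predicted - annotated)
}

#' Tolerance-based positive prediction rate
#'
#' The fraction of recordings whose predicted time distance is within the
#' tolerance. Undetected recordings (`NA` distance) stay in the denominator.
#' The paper's headline metric is the 5-second rate, PPR_5s.
#'
#' @param td Numeric vector of time distances (may contain `NA`).
#' @param tolerance Tolerance in seconds (default 5).
#' @return Rate in `[0, 1]`.
#' @export
ppr_at_tolerance <- function(td, tolerance = 5) {
  if (length(td) == 0) {
    abort("Need at least one recording.", class = "pges_parameter_error")
  }
  mean(!is.na(td) & td <= tolerance)
}

#' Segment-based metrics with PGES as the positive class
#'
#' Accuracy `(TP_PGES + TP_ISW) / N`, recall `TP_PGES / Num_PGES_expert`,
#' precision `TP_PGES / Num_PGES_detect`, and their F1. A ratio with a zero
#' denominator is defined as 0.
#'
#' @param annotated Integer 0/1 expert labels (0 = PGES).
#' @param predicted Integer 0/1 detected labels, same length.
#' @return One-row tibble: `accuracy`, `recall`, `precision`, `f1`.
#' @export
segment_metrics <- function(annotated, predicted) {
  if (length(annotated) != length(predicted)) {
    abort("Label sequences differ in length.", class = "pges_alignment_error")
  }
  tp_pges <- sum(annotated == 0 & predicted == 0)
  tp_isw <- sum(annotated == 1 & predicted == 1)
  n_pges_expert <- sum(annotated == 0)
  n_pges_detect <- sum(predicted == 0)
  acc <- (tp_pges + tp_isw) / length(annotated)
  rec <- if (n_pges_expert > 0) tp_pges / n_pges_expert else 0
  prec <- if (n_pges_detect > 0) tp_pges / n_pges_detect else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble::tibble(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' Artifact levels included in an evaluation group
#'
#' Nested groups: A = artifact-free only; B = A + mild; C = B + moderate;
#' D = all recordings.
#'
#' @param group One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Character vector of artifact levels.
#' @export
artifact_group_levels <- function(group) {
  lv <- c("free", "mild", "moderate", "severe")
  k <- match(toupper(group), c("A", "B", "C", "D"))
  if (is.na(k)) abort("`group` must be A, B, C or D.", class = "pges_parameter_error")
  lv[seq_len(k)]
}

annotated_labels <- function(onset, n_epochs) {
  as.integer(seq_len(n_epochs) - 1 >= onset)
}

#' Repeated grouped cross-validation of the full detection pipeline
#'
#' Recordings -- never individual epochs -- are partitioned into folds, so no
#' epoch of a test recording ever reaches training. Per fold, a balanced
#' training set is built from the training recordings
#' ([build_training_set()]), a forest is fitted, and the first-ISW onset is
#' detected over every full test recording. Metrics are computed per repeat
#' (segment metrics pooled over all test epochs of the repeat) and averaged
#' over repeats.
#'
#' @param features Stacked feature tibble (see [pges_features_dataset()]).
#' @param annotations Tibble with `recording_id`, `isw_onset_seconds`,
#'   `artifact_level`.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions with re-randomized folds (default 10).
#' @param group Artifact group A-D filtering the dataset
#'   ([artifact_group_levels()]).
#' @param n_trees,mtry,max_depth Forest parameters ([pges_rf()]).
#' @param threshold,M,hi,lo Detection read-out parameters
#'   ([detect_pges_end()]).
#' @param tolerance PPR tolerance in seconds (default 5).
#' @param seed Master seed; fold assignments and forest seeds derive from it.
#' @return A `pges_eval` object: `$summary` (one-row tibble of averaged
#'   metrics), `$by_repeat`, `$results` (per repeat x recording onsets and
#'   time distances), and the call parameters. `mean_td` averages over
#'   detected recordings; recordings with no detected ISW count as misses
#'   in `ppr` (and are tallied in `n_missed`) but cannot contribute a
#'   finite time distance.
#' @export
cross_validate <- function(features, annotations, folds = 10, repeats = 10,
                           group = "D", n_trees = 1000, mtry = NULL,
                           max_depth = 12, threshold = 0.5, M = 5, hi = 0.5,
                           lo = 0.5, tolerance = 5, seed = 1L) {
  ann <- dplyr::filter(annotations,
                       .data$artifact_level %in% artifact_group_levels(group))
  ids <- ann$recording_id
  if (length(ids) < folds) {
    abort(sprintf("Group %s has %d recordings; need at least `folds` = %d.",
                  group, length(ids), folds),
          class = "pges_parameter_error")
  }
  features <- dplyr::filter(features, .data$recording_id %in% ids)
  # index once by recording: the CV loop must not copy the full table per fold
  by_rec <- split(features, features$recording_id)
  by_rec <- lapply(by_rec, function(ft) dplyr::arrange(ft, .data$epoch))

  results <- purrr::map_dfr(seq_len(repeats), function(rep_i) {
    rep_seed <- (seed + 9973L * rep_i) %% 2147483647L
    set.seed(rep_seed)
    fold_of <- sample(rep_len(seq_len(folds), length(ids)))
    purrr::map_dfr(seq_len(folds), function(f) {
      test_ids <- ids[fold_of == f]
      train_ids <- ids[fold_of != f]
      ts <- suppressWarnings(build_training_set(
        dplyr::bind_rows(by_rec[train_ids]),
        dplyr::filter(ann, .data$recording_id %in% train_ids)))
      model <- pges_rf(ts, n_trees = n_trees, mtry = mtry,
                       max_depth = max_depth,
                       seed = (rep_seed + f) %% 2147483647L)
      purrr::map_dfr(test_ids, function(rid) {
        ft <- by_rec[[rid]]
        det <- detect_pges_end(model, ft, threshold, M, hi, lo)
        onset <- ann$isw_onset_seconds[ann$recording_id == rid][1]
        tibble::tibble(
          repeat_i = rep_i, fold = f, recording_id = rid,
          annotated_onset = onset,
          predicted_onset = det$predicted_onset,
          td = predicted_time_distance(det$predicted_onset, onset),
          labels = det$labels,
          labels_annotated = list(annotated_labels(onset, det$n_epochs))
        )
      })
    })
  })

  by_repeat <- results |>
    dplyr::group_by(.data$repeat_i) |>
    dplyr::summarise(
      ppr = ppr_at_tolerance(.data$td, tolerance),
      mean_td = mean(.data$td, na.rm = TRUE),
      n_missed = sum(is.na(.data$td)),
      seg = list(segment_metrics(unlist(.data$labels_annotated),
                                 unlist(.data$labels))),
      .groups = "drop"
    ) |>
    tidyr::unnest("seg")

  summary <- by_repeat |>
    dplyr::summarise(dplyr::across(c("ppr", "mean_td", "accuracy",
                                     "recall", "precision", "f1"), mean)) |>
    dplyr::mutate(group = group, n_recordings = length(ids),
                  folds = folds, repeats = repeats, .before = 1)

  structure(
    list(summary = summary, by_repeat = by_repeat,
         results = dplyr::select(results, -"labels", -"labels_annotated"),
         group = group, tolerance = tolerance, seed = seed),
    class = "pges_eval"
  )
}

#' @export
print.pges_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pges_eval> group %s: %d recordings, %d-fold CV x %d repeats\n",
              s$group, s$n_recordings, s$folds, s$repeats))
  cat(sprintf("  PPR_%gs %.3f | mean TD %.2f s | accuracy %.3f | F1 %.3f\n",
              x$tolerance, s$ppr, s$mean_td, s$accuracy, s$f1))
  invisible(x)
}

#' @export
glance.pges_eval <- function(x, ...) x$summary

#' @export
tidy.pges_eval <- function(x, ...) x$results

#' Histogram of per-recording time distances
#' @param object A `pges_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pges_eval <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$td))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$td)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$tolerance, linetype = "dashed") +
    ggplot2::labs(x = "predicted time distance (s)", y = "recordings",
                  title = sprintf("Group %s: PPR_%gs = %.2f",
                                  object$group, object$tolerance,
                                  object$summary$ppr)) +
    ggplot2::theme_minimal()
}
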