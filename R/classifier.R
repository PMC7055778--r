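# Segment classifier: a bagged random forest (1000 CART trees, Gini splits,
# sqrt(p) features per split) trained on balanced PGES/ISW segments and read
# out as the mean of per-tree class fractions, P(ISW).

#' Build a balanced per-recording training set
#'
#' For each annotated recording with first-ISW onset at `t` seconds (= epoch
#' index of the first ISW epoch): if `t < 30`, take the `t` ISW epochs after
#' onset, otherwise take 30; label them 1 (ISW). Take the equal number of
#' PGES epochs immediately preceding the onset, labeled 0 -- the hardest
#' negatives, and the ones the detector must get right. A recording whose
#' onset is at epoch 0 has no PGES epochs and is excluded with a warning.
#'
#' @param features Stacked feature tibble with `recording_id`, `epoch`
#'   (0-based seconds) and the 612 feature columns (see [pges_features()]).
#' @param annotations Tibble with `recording_id` and `isw_onset_seconds`.
#' @return A tibble of selected rows with a `label` column (0 = PGES,
#'   1 = ISW) after `recording_id` and `epoch`; class `pges_training_set`.
#' @export
build_training_set <- function(features, annotations) {
  ann <- dplyr::distinct(annotations, .data$recording_id, .keep_all = TRUE)
  by_rec <- split(features, factor(features$recording_id))
  picks <- purrr::map_dfr(seq_len(nrow(ann)), function(i) {
    rid <- ann$recording_id[i]
    onset <- ann$isw_onset_seconds[i]
    rows <- by_rec[[rid]]
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    if (is.na(onset) || onset <= 0) {
      warn(sprintf("Recording %s: onset at 0 s leaves no PGES segments; excluded.", rid))
      return(NULL)
    }
    n_ep <- nrow(rows)
    k <- min(if (onset < 30) onset else 30, n_ep - onset)
    if (k <= 0) {
      warn(sprintf("Recording %s: no post-onset segments; excluded.", rid))
      return(NULL)
    }
    isw <- dplyr::filter(rows, .data$epoch >= onset, .data$epoch < onset + k)
    pges <- dplyr::filter(rows, .data$epoch >= onset - k, .data$epoch < onset)
    dplyr::bind_rows(
      dplyr::mutate(pges, label = 0L, .after = "epoch"),
      dplyr::mutate(isw, label = 1L, .after = "epoch")
    )
  })
  class(picks) <- c("pges_training_set", class(picks))
  picks
}

# internal: syntactic names for the forest backend, original schema kept
rf_safe_names <- function(nms) paste0("f", seq_along(nms))

#' Train the bagged random-forest segment classifier
#'
#' Fits `n_trees` CART trees, each on a bootstrap resample of the training
#' segments with a random subset of `mtry` features considered at every
#' split, and averages tree outputs at prediction time. The out-of-bag
#' samples of each tree provide an internal, unbiased test-error estimate,
#' so no additional cross-validation is needed for model assessment.
#'
#' @param training_set Output of [build_training_set()] (or any tibble with
#'   a 0/1 `label` column and the 612 feature columns).
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @param max_depth Tree depth cap (default 12; 0 = unlimited). Post-onset
#'   epochs falling in the gaps between slow-wave bursts carry ISW labels
#'   but suppression-like signal, so fully grown trees spend most of their
#'   depth memorizing that label noise; a moderate cap leaves the ensemble's
#'   decisions on clear segments unchanged.
#' @param seed Integer seed; fixed seed gives identical models.
#' @return A `pges_model`: the fitted forest plus the feature schema,
#'   out-of-bag error estimates and training parameters.
#' @export
pges_rf <- function(training_set, n_trees = 1000, mtry = NULL,
                    max_depth = 12, seed = 1L) {
  lab <- training_set$label
  if (length(unique(lab)) < 2) {
    abort("Training data contain a single class; need both PGES and ISW segments.",
          class = "pges_training_error")
  }
  schema <- intersect(feature_columns(), names(training_set))
  if (length(schema) == 0) {
    abort("No recognised feature columns in the training set.",
          class = "pges_feature_error")
  }
  x <- as.data.frame(training_set[schema])
  names(x) <- rf_safe_names(schema)
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(x)))
  fit <- ranger::ranger(
    x = x, y = factor(lab, levels = c(0, 1)),
    num.trees = n_trees, mtry = mtry, probability = TRUE,
    max.depth = max_depth, seed = seed, num.threads = 1, verbose = FALSE
  )
  oob_prob <- fit$predictions[, "1"]
  ok <- !is.na(oob_prob)
  oob_err <- mean((oob_prob[ok] >= 0.5) != (lab[ok] == 1))
  structure(
    list(forest = fit, schema = schema, n_trees = n_trees, mtry = mtry,
         max_depth = max_depth, seed = seed, oob_error = oob_err,
         oob_brier = fit$prediction.error, n_train = nrow(x)),
    class = "pges_model"
  )
}

#' @export
print.pges_model <- function(x, ...) {
  cat(sprintf("<pges_model> random forest, %d trees, mtry %d, %d segments\n",
              x$n_trees, x$mtry, x$n_train))
  cat(sprintf("  out-of-bag misclassification: %.3f (Brier %.3f)\n",
              x$oob_error, x$oob_brier))
  invisible(x)
}

#' @export
glance.pges_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, mtry = x$mtry, n_train = x$n_train,
                 oob_error = x$oob_error, oob_brier = x$oob_brier)
}

#' Per-epoch ISW probabilities
#'
#' Averages the class fractions of all trees for every row of the feature
#' table, giving `P(ISW)` per epoch.
#'
#' @param model A [pges_rf()] model.
#' @param features Feature tibble with the same 612 feature columns as the
#'   training data (extra metadata columns such as `recording_id`, `epoch`
#'   are ignored).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "pges_model"))
  present <- intersect(feature_columns(), names(features))
  missing <- setdiff(model$schema, present)
  extra <- setdiff(present, model$schema)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "Feature columns do not match the training schema.",
      if (length(missing)) sprintf(" Missing: %s.",
                                   paste(head(missing, 5), collapse = ", ")),
      if (length(extra)) sprintf(" Extra: %s.",
                                 paste(head(extra, 5), collapse = ", "))
    ), class = "pges_feature_error")
  }
  x <- as.data.frame(features[model$schema])
  names(x) <- rf_safe_names(model$schema)
  unname(predict(model$forest, data = x, num.threads = 1)$predictions[, "1"])
}

#' Threshold probabilities into PGES/ISW labels
#'
#' @param probs Numeric vector of `P(ISW)` values.
#' @param threshold Classification threshold in (0, 1); ties (`prob ==
#'   threshold`) go to ISW.
#' @return Integer vector of labels, 0 = PGES, 1 = ISW.
#' @export
predict_labels <- function(probs, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) {
    abort("`threshold` must lie in (0, 1).", class = "pges_parameter_error")
  }
  as.integer(probs >= threshold)
}
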