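#' Balanced accuracy rate
#'
#' The average of sensitivity and specificity, with "progressive" as the
#' positive class: \eqn{(TP/(TP+FN) + TN/(TN+FP)) / 2}. A perfect classifier
#' scores 1, a label-independent random classifier 0.5 in expectation, and
#' a classifier that always predicts one class also 0.5.
#'
#' @param true_labels,predicted_labels Character vectors over
#'   `"progressive"` / `"responsive"`, same length; both classes must occur
#'   in `true_labels`.
#' @return A single number in `[0, 1]`.
#' @examples
#' bar(c("progressive", "progressive", "progressive", "responsive"),
#'     c("progressive", "progressive", "responsive", "responsive"))  # 5/6
#' @export
bar <- function(true_labels, predicted_labels) {
  cm <- confusion_counts(true_labels, predicted_labels)
  bar_from_counts(cm)
}

confusion_counts <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("label vectors must have the same length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), CLASS_LEVELS)
  if (length(bad)) abort(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  if (length(unique(true_labels)) < 2) {
    abort("both classes must be present in the true labels")
  }
  pos <- CLASS_LEVELS[1]
  c(tp = sum(true_labels == pos & predicted_labels == pos),
    fp = sum(true_labels != pos & predicted_labels == pos),
    tn = sum(true_labels != pos & predicted_labels != pos),
    fn = sum(true_labels == pos & predicted_labels != pos))
}

bar_from_counts <- function(cm) {
  sens <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  spec <- cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
  (sens + spec) / 2
}

#' Leave-one-patient-out classification of a fixed feature subset
#'
#' One fold per patient: that patient's labeled time points are the test
#' set, all remaining labeled time points the training set. Predictions are
#' pooled over all folds before a single balanced accuracy is computed, so
#' the pooled prediction count equals the number of labeled time points.
#'
#' @param features Scaled feature tibble with `patient_id` and `label`
#'   columns; only labeled rows are used.
#' @param feature_subset Character vector of feature column names to train
#'   on (e.g. the first k fused features).
#' @param spec A [classifier_spec()].
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return List with `bar`, `counts` (tp/fp/tn/fn), and `predictions`
#'   (tibble `patient_id`, `time_index`, `label`, `predicted`).
#' @export
lopocv_classify <- function(features, feature_subset, spec, seed = 1L) {
  if (!inherits(spec, "classifier_spec")) abort("`spec` must be a classifier_spec")
  labeled <- features[features$label %in% CLASS_LEVELS, ]
  missing_cols <- setdiff(feature_subset, names(labeled))
  if (length(missing_cols)) {
    abort(sprintf("feature columns not in table: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  patients <- unique(labeled$patient_id)
  if (length(patients) < 2) abort("need >= 2 patients for LOPOCV")

  preds <- purrr::map(patients, function(pat) {
    train <- labeled[labeled$patient_id != pat, ]
    test <- labeled[labeled$patient_id == pat, ]
    if (length(unique(train$label)) < 2) {
      abort(sprintf("training fold without patient %s is single-class", pat))
    }
    pred <- fit_predict(spec,
                        train[feature_subset], train$label,
                        test[feature_subset],
                        seed = derive_seed(seed, paste(spec$name, pat)))
    tibble(patient_id = test$patient_id, time_index = test$time_index,
           label = test$label, predicted = pred)
  })
  predictions <- dplyr::bind_rows(preds)
  cm <- confusion_counts(predictions$label, predictions$predicted)
  list(bar = bar_from_counts(cm), counts = cm, predictions = predictions)
}

# Feature columns of `tbl` belonging to one modality's maps.
modality_columns <- function(tbl, modality) {
  maps <- modality_maps(modality)
  cols <- setdiff(names(tbl), c("patient_id", "time_index", "label"))
  cols[sub("_.*$", "", cols) %in% maps]
}

#' Run the full delineation x modality x classifier x feature-count grid
#'
#' Evaluates every combination of delineation, MR modality, classifier and
#' number of fused features (1..10 by default) under round-2 LOPOCV, scoring
#' each cell by pooled balanced accuracy. The full benchmark is
#' 2 delineations x 4 modalities x 7 classifiers x 10 feature counts =
#' 560 cells. Feature subsets of size k are the first k fused features of
#' the cell's dataset.
#'
#' @param features Named list of scaled feature tibbles, one per delineation
#'   (`total`, `cer_ner`), each holding all 16 maps' columns.
#' @param ranked Named list of [lopocv_rank_round()] results keyed
#'   `<delineation>_<modality>` (e.g. `"cer_ner_cmri"`).
#' @param classifiers List of [classifier_spec()]s (default all seven).
#' @param delineations,modalities Grid axes (defaults: both delineations,
#'   all four modalities).
#' @param n_features Feature counts to evaluate (default `1:10`).
#' @param seed Master seed; each cell derives its own stream.
#' @return A `bar_grid` tibble: one row per cell with columns `delineation`,
#'   `modality`, `classifier`, `n_features`, `bar`, `tp`, `fp`, `tn`, `fn`.
#' @export
run_grid <- function(features, ranked,
                     classifiers = default_classifier_specs(),
                     delineations = DELINEATIONS,
                     modalities = names(MODALITY_SETS),
                     n_features = 1:10, seed = 1L) {
  if (any(n_features < 1) || any(n_features > 10)) {
    abort("`n_features` must lie in 1..10")
  }
  needed <- as.vector(outer(delineations, modalities, paste, sep = "_"))
  gap <- setdiff(needed, names(ranked))
  if (length(gap)) {
    abort(sprintf("missing ranked feature sets for dataset(s): %s",
                  paste(gap, collapse = ", ")))
  }
  gap2 <- setdiff(delineations, names(features))
  if (length(gap2)) {
    abort(sprintf("missing feature tables for delineation(s): %s",
                  paste(gap2, collapse = ", ")))
  }

  rows <- list()
  for (del in delineations) {
    tbl <- features[[del]]
    for (mod in modalities) {
      tag <- paste(del, mod, sep = "_")
      fused <- ranked[[tag]]$fused$feature
      for (spec in classifiers) {
        for (k in n_features) {
          kk <- min(k, length(fused))
          res <- lopocv_classify(
            tbl, fused[seq_len(kk)], spec,
            seed = derive_seed(seed, paste(tag, spec$name, k)))
          rows[[length(rows) + 1L]] <- tibble(
            delineation = del, modality = mod, classifier = spec$name,
            n_features = as.integer(k), bar = res$bar,
            tp = res$counts[["tp"]], fp = res$counts[["fp"]],
            tn = res$counts[["tn"]], fn = res$counts[["fn"]])
        }
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  class(grid) <- c("bar_grid", class(grid))
  grid
}
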