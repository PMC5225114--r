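#' Fuse many feature rankings with rank products
#'
#' The candidate set is every feature appearing in the top `top_k` of at
#' least one ranking. Each candidate is scored by the geometric mean of its
#' rank positions across *all* rankings (order-equivalent to the raw rank
#' product but immune to overflow over hundreds of rankings); ranks outside
#' the top `top_k` still contribute their full position. The `top_k`
#' lowest-scoring candidates are returned in ascending score order, ties
#' broken lexicographically by feature name.
#'
#' @param rankings A list of ranking tibbles as returned by
#'   [rank_features()] (columns `feature`, `rank`), all over the same
#'   feature universe.
#' @param top_k Size of the fused set (default 10).
#' @return An object of class `ranked_feature_set`: list with `fused`
#'   (tibble `feature`, `score`), `n_rankings`, and optionally `dataset`.
#' @examples
#' r1 <- tibble::tibble(feature = c("a", "b", "c"), rank = 1:3)
#' r2 <- tibble::tibble(feature = c("b", "a", "c"), rank = 1:3)
#' rank_product_fuse(list(r1, r2), top_k = 2)
#' @export
rank_product_fuse <- function(rankings, top_k = 10L) {
  if (!length(rankings)) abort("empty list of rankings")
  universe <- sort(rankings[[1]]$feature)
  rank_mat <- vapply(rankings, function(r) {
    if (!setequal(r$feature, universe)) {
      abort("all rankings must cover the same feature universe")
    }
    r$rank[match(universe, r$feature)]
  }, numeric(length(universe)))
  rank_mat <- matrix(rank_mat, nrow = length(universe))

  in_top <- rowSums(rank_mat <= top_k) > 0
  score <- exp(rowMeans(log(rank_mat)))
  cand <- tibble(feature = universe, score = score)[in_top, ]
  cand <- cand[order(cand$score, cand$feature), ]
  fused <- head(cand, top_k)
  structure(
    list(fused = as_tibble(fused), n_rankings = length(rankings),
         top_k = as.integer(top_k), dataset = NULL),
    class = "ranked_feature_set"
  )
}

#' @export
print.ranked_feature_set <- function(x, ...) {
  cat(sprintf("<ranked_feature_set>%s fused from %d rankings\n",
              if (is.null(x$dataset)) "" else paste0(" [", x$dataset, "]"),
              x$n_rankings))
  print(x$fused)
  invisible(x)
}

#' Round-1 LOPOCV feature ranking and rank-product fusion
#'
#' For every leave-one-patient-out fold, each requested ranker is fit on the
#' labeled time points of the training patients, yielding
#' `length(methods) * n_patients` complete rankings (174 in the reference
#' setting of 29 patients and 6 methods); all of them are fused into one
#' fixed top-`top_k` feature set by [rank_product_fuse()].
#'
#' @param features Feature tibble ([extract_features()] output, scaled),
#'   containing `patient_id` and `label` columns; only rows labeled
#'   progressive/responsive are used for ranking.
#' @param methods Ranker names (see [rank_features()]); default all six.
#' @param top_k Fused set size (default 10).
#' @param seed Master seed; per-(fold, method) seeds are derived from it.
#' @param dataset Optional tag naming the dataset (delineation x modality).
#' @param ... Passed on to [rank_features()] (e.g. `n_trees`).
#' @return A `ranked_feature_set` with the per-fold rankings attached as
#'   `rankings` (tibble with `fold`, `method`, `feature`, `rank`).
#' @export
lopocv_rank_round <- function(features,
                              methods = c("mRMR", "ReliefF", "InfoGain",
                                          "Chi2", "RF_MDA", "RF_MDG"),
                              top_k = 10L, seed = 1L, dataset = NULL, ...) {
  labeled <- features[features$label %in% CLASS_LEVELS, ]
  patients <- unique(labeled$patient_id)
  if (length(patients) < 2) abort("need >= 2 patients for LOPOCV")
  feat_cols <- setdiff(names(features),
                       c("patient_id", "time_index", "label"))

  all_rankings <- list()
  per_fold <- list()
  for (pat in patients) {
    train <- labeled[labeled$patient_id != pat, ]
    if (length(unique(train$label)) < 2) {
      abort(sprintf("training fold without patient %s is single-class", pat))
    }
    for (m in methods) {
      r <- rank_features(train[feat_cols], train$label, method = m,
                         seed = derive_seed(seed, paste(pat, m)), ...)
      all_rankings[[length(all_rankings) + 1L]] <- r
      per_fold[[length(per_fold) + 1L]] <- dplyr::mutate(r, fold = pat,
                                                         .before = 1)
    }
  }
  out <- rank_product_fuse(all_rankings, top_k = top_k)
  out$dataset <- dataset
  out$rankings <- dplyr::bind_rows(per_fold)
  out
}
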