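#' Catalog of the 26 per-map, per-ROI features
#'
#' Six histogram measures plus the 20 co-occurrence texture features, in the
#' fixed order used for feature naming. Column names in feature tables are
#' `<map>_<feature>_<roi>`, e.g. `T1pc_p90_cer`.
#'
#' @return List with character vectors `histogram` (length 6) and `texture`
#'   (length 20).
#' @export
feature_catalog <- function() {
  list(
    histogram = c("mean", "coefficient_of_variation", "p90", "p10",
                  "skewness", "kurtosis"),
    texture = c("autocorrelation", "contrast", "correlation",
                "cluster_prominence", "cluster_shade", "dissimilarity",
                "energy", "entropy", "homogeneity", "maximum_probability",
                "sum_of_squares_variance", "sum_average", "sum_variance",
                "sum_entropy", "difference_variance", "difference_entropy",
                "imc1", "imc2", "idn", "idmn")
  )
}

#' Normalize ROI intensities to a NAWM reference
#'
#' @param map 3-D numeric array.
#' @param roi Logical (or 0/1) mask of the same dimensions.
#' @param reference Nonzero scalar, typically [nawm_reference()] of the same map.
#' @return Numeric vector of length `sum(roi)`: ROI intensities divided by
#'   the reference.
#' @export
normalize_roi <- function(map, roi, reference) {
  roi <- roi > 0
  if (!identical(dim(map), dim(roi))) abort("`map` and `roi` must share dimensions")
  if (!any(roi)) abort("empty ROI")
  if (!is.finite(reference) || reference == 0) {
    abort("normalization reference must be finite and nonzero")
  }
  map[roi] / reference
}

#' The six histogram features of an intensity sample
#'
#' Mean, coefficient of variation (population SD over mean), 90th and 10th
#' percentiles (linear-interpolation convention, [stats::quantile()] type 7),
#' skewness (third standardized moment) and kurtosis (fourth standardized
#' moment, non-excess: a normal sample gives ~3). All moments use the
#' population (n-denominator) convention. A zero-variance sample reports
#' CV, skewness and kurtosis as 0.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector of length 6 in catalog order.
#' @export
histogram_features <- function(values) {
  if (length(values) < 2) abort("need at least 2 values for histogram features")
  if (any(!is.finite(values))) abort("non-finite intensity values")
  m <- mean(values)
  v <- mean((values - m)^2)           # population variance
  if (m == 0 && v > 0) abort("mean is zero: coefficient of variation undefined")
  if (v == 0) {
    cv <- 0; skw <- 0; krt <- 0
  } else {
    s <- sqrt(v)
    cv <- s / m
    skw <- mean((values - m)^3) / s^3
    krt <- mean((values - m)^4) / s^4
  }
  c(mean = m,
    coefficient_of_variation = cv,
    p90 = unname(quantile(values, 0.90, type = 7)),
    p10 = unname(quantile(values, 0.10, type = 7)),
    skewness = skw,
    kurtosis = krt)
}

#' Quantize intensities onto integer gray levels 1..n_levels
#'
#' Linear min-max map of the sample onto `[1, n_levels]`, rounded half-up:
#' the minimum maps to level 1, the maximum to level `n_levels`. A constant
#' sample maps entirely to level 1.
#'
#' @param values Numeric vector (the ROI's normalized intensities).
#' @param n_levels Number of levels (default 64).
#' @return Integer vector of the same length with values in `1..n_levels`.
#' @examples
#' rescale_levels(c(0, 0.5, 1))  # 1, 33, 64
#' @export
rescale_levels <- function(values, n_levels = 64L) {
  if (!length(values)) abort("empty input")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  x <- 1 + (n_levels - 1) * (values - lo) / (hi - lo)
  lv <- as.integer(floor(x + 0.5))    # round half-up
  pmin.int(pmax.int(lv, 1L), n_levels)
}

# The 26 features of one (map, ROI) pair from already-normalized intensities.
roi_features <- function(norm_values, roi, shape, n_levels = 64L) {
  hist_f <- histogram_features(norm_values)
  lv <- array(NA_integer_, dim = shape)
  lv[roi] <- rescale_levels(norm_values, n_levels)
  glcm <- build_cooccurrence(lv, roi, n_levels)
  c(hist_f, texture_features(glcm))
}

#' Extract the named feature vector of one time point
#'
#' For each requested ROI and each requested parameter map: divide the ROI
#' voxels by the map's NAWM mean, compute the 6 histogram features on the
#' normalized intensities, quantize the same intensities onto 64 gray levels,
#' build the in-plane co-occurrence matrix and compute the 20 texture
#' features. With all 16 maps this yields 416 features per ROI (26 x 16):
#' 416 for the `total` delineation, 832 for `cer_ner` (CER and NER each
#' contribute 416).
#'
#' @param timepoint A `gbm_timepoint` (16 maps plus total and NAWM masks).
#' @param delineation `"total"` (whole-tumor ROI) or `"cer_ner"` (the
#'   percentile split of [split_total()]).
#' @param maps Character vector of map names to use (default all 16).
#' @param percentile Percentile for the CER/NER split (default 0.90).
#' @param n_levels Gray levels for the GLCM (default 64).
#' @return Named numeric vector, names `<map>_<feature>_<roi>` in
#'   deterministic order (ROI outer, map middle, feature inner).
#' @export
extract_timepoint <- function(timepoint, delineation = c("total", "cer_ner"),
                              maps = MAP_NAMES, percentile = 0.90,
                              n_levels = 64L) {
  delineation <- match.arg(delineation)
  if (!all(maps %in% MAP_NAMES)) abort("unknown map name(s)")
  if (!all(maps %in% names(timepoint$maps))) abort("time point is missing requested maps")
  shape <- dim(timepoint$total_mask)

  rois <- if (delineation == "total") {
    list(total = timepoint$total_mask > 0)
  } else {
    rs <- split_total(timepoint$maps[["T1pc"]], timepoint$total_mask, percentile)
    list(cer = rs$cer, ner = rs$ner)
  }

  out <- numeric(0)
  for (roi_name in names(rois)) {
    roi <- rois[[roi_name]]
    for (m in maps) {
      ref <- nawm_reference(timepoint$maps[[m]], timepoint$nawm_mask)
      vals <- normalize_roi(timepoint$maps[[m]], roi, ref)
      feats <- tryCatch(
        roi_features(vals, roi, shape, n_levels),
        error = function(e) {
          abort(sprintf("feature extraction failed for map %s, ROI %s: %s",
                        m, roi_name, conditionMessage(e)))
        })
      names(feats) <- paste(m, names(feats), roi_name, sep = "_")
      out <- c(out, feats)
    }
  }
  out
}

#' Extract the feature table of a whole cohort
#'
#' Applies [extract_timepoint()] to every time point (labeled and unlabeled)
#' and assembles one tibble with identifier columns `patient_id`,
#' `time_index`, `label` followed by the feature columns.
#'
#' @inheritParams extract_timepoint
#' @param cohort A `gbm_cohort`.
#' @param modality Optional shorthand for `maps`: one of `"cmri"`, `"pwi"`,
#'   `"dki"`, `"cpd"` (overrides `maps` if given).
#' @return A tibble, one row per time point.
#' @export
extract_features <- function(cohort, delineation = c("total", "cer_ner"),
                             maps = MAP_NAMES, modality = NULL,
                             percentile = 0.90, n_levels = 64L) {
  delineation <- match.arg(delineation)
  if (!inherits(cohort, "gbm_cohort")) abort("`cohort` must be a gbm_cohort")
  if (!is.null(modality)) maps <- modality_maps(modality)
  rows <- purrr::map(cohort$timepoints, function(tp) {
    fv <- extract_timepoint(tp, delineation, maps, percentile, n_levels)
    dplyr::bind_cols(
      tibble(patient_id = tp$patient_id, time_index = tp$time_index,
             label = tp$label),
      as_tibble(as.list(fv))
    )
  })
  dplyr::bind_rows(rows)
}

#' Min-max scale feature columns to [0, 1] over a scaling population
#'
#' Per-column linear rescaling so the scaling population spans exactly
#' `[0, 1]`; applied to all rows. The scaling population defaults to every
#' row — labeled and unlabeled time points alike, matching a cohort-wide
#' normalization done before any cross-validation split (the faithful
#' reproduction of the original procedure; note this leaks marginal scale
#' across folds). Pass `population` to restrict it, e.g. to training rows
#' only, for a fold-safe variant. Constant columns map to 0.
#'
#' @param table Feature tibble as returned by [extract_features()].
#' @param population Optional logical/integer row index of the scaling
#'   population (default: all rows).
#' @param id_cols Columns excluded from scaling.
#' @return The tibble with all feature columns rescaled.
#' @export
scale_features <- function(table, population = NULL,
                           id_cols = c("patient_id", "time_index", "label")) {
  feat_cols <- setdiff(names(table), id_cols)
  pop <- if (is.null(population)) seq_len(nrow(table)) else population
  if (length(seq_len(nrow(table))[pop]) < 2) abort("scaling population needs >= 2 rows")
  table[feat_cols] <- lapply(table[feat_cols], function(col) {
    lo <- min(col[pop]); hi <- max(col[pop])
    if (hi == lo) rep(0, length(col)) else (col - lo) / (hi - lo)
  })
  table
}
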