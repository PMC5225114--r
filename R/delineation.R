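#' Split the whole-tumor ROI into enhancing and non-enhancing regions
#'
#' Thresholds the post-contrast T1 (T1pc) intensities of the whole-tumor
#' (Total) mask at a percentile (default the 90th) and partitions Total into
#' the contrast-enhancing region (CER: voxels strictly above the threshold)
#' and the non-enhancing region (NER: the rest). The percentile is computed
#' with linear interpolation between order statistics
#' ([stats::quantile()] type 7); ties at the threshold fall into NER, so
#' `|CER| <= (1 - percentile) * |Total|` always holds.
#'
#' @param t1pc 3-D numeric array of T1pc intensities.
#' @param total Logical (or 0/1) array of the same dimensions: whole-tumor mask.
#' @param percentile Fraction in (0, 1); default 0.90.
#' @return An object of class `roi_set`: list with logical arrays `total`,
#'   `cer`, `ner` and the numeric `threshold_value`. CER and NER are disjoint
#'   and their union is Total.
#' @examples
#' t1pc <- array(1:1000, dim = c(10, 10, 10))
#' total <- array(FALSE, dim = c(10, 10, 10)); total[1:100] <- TRUE
#' rois <- split_total(t1pc, total)
#' sum(rois$cer)  # 10 voxels above the interpolated 90th percentile
#' @export
split_total <- function(t1pc, total, percentile = 0.90) {
  total <- total > 0
  if (!identical(dim(t1pc), dim(total))) {
    abort("`t1pc` and `total` must share dimensions")
  }
  if (!any(total)) abort("empty Total mask")
  if (percentile <= 0 || percentile >= 1) abort("`percentile` must be in (0, 1)")
  vals <- t1pc[total]
  if (any(!is.finite(vals))) abort("non-finite T1pc intensities inside Total")
  thr <- unname(quantile(vals, percentile, type = 7))
  cer <- total & (t1pc > thr)
  if (!any(cer)) {
    abort("degenerate split: no Total voxel exceeds the percentile threshold (constant T1pc?)")
  }
  ner <- total & !cer
  structure(
    list(total = total, cer = cer, ner = ner, threshold_value = thr,
         percentile = percentile),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> |Total| = %d, |CER| = %d, |NER| = %d, threshold = %.4g\n",
              sum(x$total), sum(x$cer), sum(x$ner), x$threshold_value))
  invisible(x)
}

#' NAWM reference intensity
#'
#' Arithmetic mean of a parameter map over the contralateral
#' normal-appearing-white-matter mask; the per-map reference every tumor ROI
#' is normalized against.
#'
#' @param map 3-D numeric array.
#' @param nawm Logical (or 0/1) mask of the same dimensions.
#' @return A single numeric intensity.
#' @export
nawm_reference <- function(map, nawm) {
  nawm <- nawm > 0
  if (!identical(dim(map), dim(nawm))) abort("`map` and `nawm` must share dimensions")
  if (!any(nawm)) abort("empty NAWM mask")
  ref <- mean(map[nawm])
  if (!is.finite(ref) || ref == 0) {
    abort("NAWM reference is zero or non-finite; cannot normalize")
  }
  ref
}
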