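#' Build a gray-level co-occurrence matrix over a 3-D ROI
#'
#' Counts co-occurring quantized intensity pairs at distance 1 for the four
#' in-plane directions (0, 45, 90, 135 degrees), slice by axial slice, keeping
#' only pairs whose two voxels both lie inside the ROI. Counts are
#' accumulated symmetrically (each pair contributes to \eqn{C(i,j)} and
#' \eqn{C(j,i)}), summed over all slices and directions into a single
#' `n_levels` x `n_levels` matrix, then normalized to probabilities.
#' Through-plane offsets are deliberately excluded: clinical acquisitions are
#' anisotropic, with slice spacing well above in-plane resolution.
#'
#' @param levels 3-D integer array of quantized levels (values in
#'   `1..n_levels` inside the ROI; anything outside the ROI is ignored).
#' @param roi Logical (or 0/1) array of the same dimensions.
#' @param n_levels Number of gray levels (default 64).
#' @return An object of class `glcm`: list with the normalized symmetric
#'   probability matrix `P`, the raw `counts`, and `n_levels`.
#' @export
build_cooccurrence <- function(levels, roi, n_levels = 64L) {
  roi <- roi > 0
  if (!identical(dim(levels), dim(roi))) {
    abort("`levels` and `roi` must share dimensions")
  }
  lv <- levels[roi]
  if (length(lv) && (any(lv < 1) || any(lv > n_levels))) {
    abort(sprintf("levels inside the ROI must lie in 1..%d", n_levels))
  }
  counts <- matrix(0, n_levels, n_levels)
  # Matlab graycomatrix offsets in (row, col) order for 0/45/90/135 degrees
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  lv3 <- levels
  lv3[!roi] <- NA_integer_
  slice_has_roi <- apply(roi, 3, any)
  nr <- dim(lv3)[1]; nc <- dim(lv3)[2]
  for (z in which(slice_has_roi)) {
    sl <- matrix(lv3[, , z], nr, nc)
    for (off in offsets) {
      di <- off[1]; dj <- off[2]
      r0 <- max(1L, 1L - di); r1 <- min(nr, nr - di)
      c0 <- max(1L, 1L - dj); c1 <- min(nc, nc - dj)
      if (r0 > r1 || c0 > c1) next
      ri <- r0:r1
      ci <- c0:c1
      a <- sl[ri, ci, drop = FALSE]
      b <- sl[ri + di, ci + dj, drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      ij <- (a[ok] - 1L) * n_levels + b[ok]          # column-of-b within row-of-a
      tab <- tabulate(ij, nbins = n_levels * n_levels)
      m <- matrix(tab, n_levels, n_levels, byrow = TRUE)
      counts <- counts + m + t(m)
    }
  }
  tot <- sum(counts)
  if (tot == 0) {
    abort("ROI has no in-slice neighboring voxel pair; GLCM is empty")
  }
  structure(list(P = counts / tot, counts = counts, n_levels = n_levels),
            class = "glcm")
}

# -log2 entropy helper with the 0 * log 0 == 0 convention
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 20 co-occurrence (Haralick-family) texture features
#'
#' Evaluates the 20 statistics of the Haralick, Soh-Tsatsoulis and Clausi
#' families on a normalized symmetric GLCM: autocorrelation, contrast,
#' correlation, cluster prominence, cluster shade, dissimilarity, energy,
#' entropy, homogeneity, maximum probability, sum of squares: variance,
#' sum average, sum variance, sum entropy, difference variance, difference
#' entropy, the two information measures of correlation (IMC1, IMC2), inverse
#' difference normalized (IDN) and inverse difference moment normalized
#' (IDMN). Entropy-type features use base-2 logarithms with
#' \eqn{0 \log 0 = 0}. On a degenerate GLCM with zero marginal variance
#' (single occupied level) correlation, IMC1 and IMC2 are reported as 0.
#'
#' @param glcm A [build_cooccurrence()] result (or a bare normalized matrix).
#' @return Named numeric vector of length 20, in catalog order
#'   (see [feature_catalog()]).
#' @export
texture_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else as.matrix(glcm)
  n <- nrow(P)
  if (abs(sum(P) - 1) > 1e-8) abort("GLCM must be normalized to sum 1")
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)                      # == colSums(P) for symmetric input
  py <- colSums(P)
  mu_x <- sum(seq_len(n) * px)
  mu_y <- sum(seq_len(n) * py)
  sd_x <- sqrt(sum((seq_len(n) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(n) - mu_y)^2 * py))

  d <- abs(i - j)
  s <- i + j
  # p_{x+y}(k), k = 2..2n ; p_{x-y}(k), k = 0..n-1
  p_sum <- vapply(2:(2 * n), function(k) sum(P[s == k]), numeric(1))
  k_sum <- 2:(2 * n)
  p_diff <- vapply(0:(n - 1), function(k) sum(P[d == k]), numeric(1))
  k_diff <- 0:(n - 1)

  autocorrelation <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (autocorrelation - mu_x * mu_y) / (sd_x * sd_y) else 0
  cluster_prominence <- sum((s - mu_x - mu_y)^4 * P)
  cluster_shade <- sum((s - mu_x - mu_y)^3 * P)
  dissimilarity <- sum(d * P)
  energy <- sum(P^2)
  entropy <- entropy_bits(P)
  homogeneity <- sum(P / (1 + d))
  maximum_probability <- max(P)
  sum_of_squares_variance <- sum((i - mu_x)^2 * P)
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- entropy_bits(p_sum)
  diff_mean <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - diff_mean)^2 * p_diff)
  difference_entropy <- entropy_bits(p_diff)

  hxy <- entropy
  hx <- entropy_bits(px)
  hy <- entropy_bits(py)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- entropy_bits(pxpy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (sd_x > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0

  idn <- sum(P / (1 + d / n))
  idmn <- sum(P / (1 + d^2 / n^2))

  c(autocorrelation = autocorrelation, contrast = contrast,
    correlation = correlation, cluster_prominence = cluster_prominence,
    cluster_shade = cluster_shade, dissimilarity = dissimilarity,
    energy = energy, entropy = entropy, homogeneity = homogeneity,
    maximum_probability = maximum_probability,
    sum_of_squares_variance = sum_of_squares_variance,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    idn = idn, idmn = idmn)
}
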