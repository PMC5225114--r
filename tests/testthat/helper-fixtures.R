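# Small cohort configurations used across tests; grids are kept small so the
# suite stays fast while preserving the cohort's statistical structure.
tiny_config <- function(seed = 1, effect_size = 1, n_patients = 4,
                        labeled = 8, ratio = 0.5, grid = c(20, 20, 10),
                        n_unlabeled = 1) {
  cohort_config(n_patients = n_patients, labeled_timepoints_total = labeled,
                class_ratio = ratio, n_unlabeled = n_unlabeled,
                grid_shape = grid, seed = seed, effect_size = effect_size)
}

# Brute-force GLCM oracle: double loop over every voxel pair, checking each
# of the four in-plane offsets in both directions.
naive_glcm <- function(levels, roi, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  dims <- dim(roi)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  idx <- which(roi, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    x <- idx[v, 1]; y <- idx[v, 2]; z <- idx[v, 3]
    for (off in offsets) {
      for (sgn in c(1, -1)) {
        x2 <- x + sgn * off[1]; y2 <- y + sgn * off[2]
        if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2]) next
        if (!roi[x2, y2, z]) next
        a <- levels[x, y, z]; b <- levels[x2, y2, z]
        counts[a, b] <- counts[a, b] + 1
      }
    }
  }
  counts / sum(counts)
}

# Independent naive evaluation of the 20 texture statistics by direct
# summation over all (i, j) cells, no vectorization shared with the package.
naive_texture <- function(P) {
  n <- nrow(P)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- 0; mu_y <- 0
  for (i in 1:n) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  var_x <- 0; var_y <- 0
  for (i in 1:n) { var_x <- var_x + (i - mu_x)^2 * px[i]
                   var_y <- var_y + (i - mu_y)^2 * py[i] }
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)

  out <- c(autocorrelation = 0, contrast = 0, correlation = 0,
           cluster_prominence = 0, cluster_shade = 0, dissimilarity = 0,
           energy = 0, entropy = 0, homogeneity = 0, maximum_probability = 0,
           sum_of_squares_variance = 0, sum_average = 0, sum_variance = 0,
           sum_entropy = 0, difference_variance = 0, difference_entropy = 0,
           imc1 = 0, imc2 = 0, idn = 0, idmn = 0)
  p_sum <- rep(0, 2 * n); p_diff <- rep(0, n)   # indices k and k+1
  for (i in 1:n) for (j in 1:n) {
    pij <- P[i, j]
    out["autocorrelation"] <- out["autocorrelation"] + i * j * pij
    out["contrast"] <- out["contrast"] + (i - j)^2 * pij
    out["cluster_prominence"] <- out["cluster_prominence"] +
      (i + j - mu_x - mu_y)^4 * pij
    out["cluster_shade"] <- out["cluster_shade"] +
      (i + j - mu_x - mu_y)^3 * pij
    out["dissimilarity"] <- out["dissimilarity"] + abs(i - j) * pij
    out["energy"] <- out["energy"] + pij^2
    out["entropy"] <- out["entropy"] - pij * lg2(pij)
    out["homogeneity"] <- out["homogeneity"] + pij / (1 + abs(i - j))
    out["maximum_probability"] <- max(out["maximum_probability"], pij)
    out["sum_of_squares_variance"] <- out["sum_of_squares_variance"] +
      (i - mu_x)^2 * pij
    out["idn"] <- out["idn"] + pij / (1 + abs(i - j) / n)
    out["idmn"] <- out["idmn"] + pij / (1 + (i - j)^2 / n^2)
    p_sum[i + j] <- p_sum[i + j] + pij
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + pij
  }
  if (sd_x > 0 && sd_y > 0) {
    out["correlation"] <- (out[["autocorrelation"]] - mu_x * mu_y) / (sd_x * sd_y)
  }
  sa <- 0
  for (k in 2:(2 * n)) sa <- sa + k * p_sum[k]
  out["sum_average"] <- sa
  for (k in 2:(2 * n)) {
    out["sum_variance"] <- out["sum_variance"] + (k - sa)^2 * p_sum[k]
    out["sum_entropy"] <- out["sum_entropy"] - p_sum[k] * lg2(p_sum[k])
  }
  dm <- 0
  for (k in 0:(n - 1)) dm <- dm + k * p_diff[k + 1]
  for (k in 0:(n - 1)) {
    out["difference_variance"] <- out["difference_variance"] +
      (k - dm)^2 * p_diff[k + 1]
    out["difference_entropy"] <- out["difference_entropy"] -
      p_diff[k + 1] * lg2(p_diff[k + 1])
  }
  hx <- 0; hy <- 0; hxy <- out[["entropy"]]; hxy1 <- 0; hxy2 <- 0
  for (i in 1:n) { hx <- hx - px[i] * lg2(px[i]); hy <- hy - py[i] * lg2(py[i]) }
  for (i in 1:n) for (j in 1:n) {
    if (P[i, j] > 0 && px[i] * py[j] > 0) {
      hxy1 <- hxy1 - P[i, j] * lg2(px[i] * py[j])
    }
    hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  if (max(hx, hy) > 0) out["imc1"] <- (hxy - hxy1) / max(hx, hy)
  if (sd_x > 0) out["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out
}

# Random small ROI + quantized levels for GLCM property tests.
random_levels_roi <- function(seed, dims = c(6, 6, 3), n_levels = 4) {
  set.seed(seed)
  roi <- array(runif(prod(dims)) < 0.6, dim = dims)
  levels <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  list(levels = levels, roi = roi, n_levels = n_levels)
}

# Synthetic feature tibble with a known informative column; used by ranking
# and classification tests that do not need image data.
synthetic_feature_table <- function(n_patients = 10, per_patient = 2,
                                    n_noise = 8, seed = 1,
                                    informative_shift = 3) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", seq_len(n_patients)), each = per_patient)
  lab <- rep(rep(c("progressive", "responsive"),
                 length.out = n_patients), each = per_patient)
  n <- length(pid)
  tbl <- tibble::tibble(
    patient_id = pid,
    time_index = rep(seq_len(per_patient), n_patients),
    label = lab,
    signal = rnorm(n) + informative_shift * (lab == "progressive")
  )
  for (k in seq_len(n_noise)) tbl[[paste0("noise", k)]] <- rnorm(n)
  tbl
}
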