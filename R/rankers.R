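# Equal-frequency discretization of a numeric feature into <= n_bins bins.
# Used by the information-theoretic rankers (InfoGain, Chi2, mRMR) in place
# of the original toolkit's unstated discretization defaults. Bin count is
# capped at ~n/5 so each bin keeps enough mass for MI/chi-square estimates
# not to saturate on small training folds.
disc_bins <- function(x, n_bins = 10L) {
  n_bins <- max(2L, min(n_bins, floor(length(x) / 5)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7, names = FALSE))
  if (length(br) <= 2) {
    # (near-)constant feature: one bin
    return(rep(1L, length(x)))
  }
  findInterval(x, br[-c(1, length(br))]) + 1L
}

# Mutual information (bits) between two integer bin vectors.
mi_bits <- function(a, b) {
  mi_all(a, matrix(b, ncol = 1))
}

# Mutual information (bits) between one integer bin vector and every column
# of an integer bin matrix, vectorized over columns: the inner loops run over
# the (few) bin levels, not over features or rows.
mi_all <- function(a, B) {
  n <- length(a)
  ka <- max(a)
  kb <- max(B)
  p <- ncol(B)
  colcounts <- matrix(0, kb, p)
  for (m in seq_len(kb)) colcounts[m, ] <- colSums(B == m)
  mi <- numeric(p)
  for (l in seq_len(ka)) {
    S <- a == l
    n_l <- sum(S)
    if (!n_l) next
    Bl <- B[S, , drop = FALSE]
    for (m in seq_len(kb)) {
      n_lm <- colSums(Bl == m)
      pos <- n_lm > 0
      mi[pos] <- mi[pos] +
        (n_lm[pos] / n) * log2((n_lm[pos] * n) / (n_l * colcounts[m, pos]))
    }
  }
  mi
}

# Chi-square statistics of every feature-bin column against the class,
# vectorized the same way as mi_all.
chi2_all <- function(y, B) {
  n <- length(y)
  classes <- unique(y)
  kb <- max(B)
  p <- ncol(B)
  colcounts <- matrix(0, kb, p)
  for (m in seq_len(kb)) colcounts[m, ] <- colSums(B == m)
  chi <- numeric(p)
  for (cl in classes) {
    S <- y == cl
    n_c <- sum(S)
    Bc <- B[S, , drop = FALSE]
    for (m in seq_len(kb)) {
      o <- colSums(Bc == m)
      e <- n_c * colcounts[m, ] / n
      pos <- e > 0
      chi[pos] <- chi[pos] + (o[pos] - e[pos])^2 / e[pos]
    }
  }
  chi
}

chi2_stat <- function(a, y) {
  chi2_all(as.character(y), matrix(a, ncol = 1))
}

# mRMR with the MID (mutual-information difference) criterion: greedily add
# the feature maximizing relevance minus mean redundancy to the selected set.
# Returns a complete ranking (every feature gets a position).
mrmr_ranking <- function(X, yb, n_bins = 10L) {
  p <- ncol(X)
  B <- vapply(seq_len(p), function(k) disc_bins(X[, k], n_bins), integer(nrow(X)))
  B <- matrix(B, nrow = nrow(X))
  rel <- mi_all(yb, B)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  order_out <- integer(p)
  for (step in seq_len(p)) {
    crit <- if (step == 1) rel[remaining]
            else rel[remaining] - red_sum[remaining] / (step - 1)
    pick <- remaining[which.max(crit)]   # which.max: ties -> lowest column index
    order_out[step] <- pick
    remaining <- remaining[remaining != pick]
    if (length(remaining)) {
      red_sum[remaining] <- red_sum[remaining] +
        mi_all(B[, pick], B[, remaining, drop = FALSE])
    }
  }
  order_out
}

# ReliefF with k nearest hits/misses per class and all instances as anchors.
# Manhattan distance on range-normalized features; miss contributions are
# weighted by class priors renormalized over the non-anchor classes.
relieff_scores <- function(X, y, k_neighbors = 10L) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2, rng, "/")
  classes <- unique(y)
  prior <- table(y) / n
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  W <- numeric(p)
  for (i in seq_len(n)) {
    for (cl in classes) {
      same <- y == cl
      pool <- which(same & seq_len(n) != i)
      pool <- pool[order(D[i, pool])]
      if (y[i] == cl) {
        hits <- head(pool, k_neighbors)
        if (length(hits)) {
          W <- W - colSums(abs(Xn[hits, , drop = FALSE] -
                               matrix(Xn[i, ], length(hits), p, byrow = TRUE))) /
                   (length(hits) * n)
        }
      } else {
        miss <- head(pool, k_neighbors)
        if (length(miss)) {
          wc <- prior[[cl]] / (1 - prior[[y[i]]])
          W <- W + wc * colSums(abs(Xn[miss, , drop = FALSE] -
                                    matrix(Xn[i, ], length(miss), p, byrow = TRUE))) /
                        (length(miss) * n)
        }
      }
    }
  }
  W
}

#' Rank features by one of six selection methods
#'
#' Produces a complete importance ranking of the feature columns under one of
#' the six rankers used by the pipeline: minimum-redundancy maximum-relevance
#' (`mRMR`, MID criterion on 10-bin equal-frequency discretized features),
#' `ReliefF` (k = 10 nearest hits/misses), information gain (`InfoGain`),
#' Pearson's chi-square (`Chi2`), and random-forest mean decrease in accuracy
#' (`RF_MDA`) or in Gini impurity (`RF_MDG`), the forests grown with 10,000
#' trees by default.
#'
#' @param X Data frame or matrix of numeric features (rows = time points).
#' @param y Class labels (two classes required).
#' @param method One of `"mRMR"`, `"ReliefF"`, `"InfoGain"`, `"Chi2"`,
#'   `"RF_MDA"`, `"RF_MDG"`.
#' @param seed Integer seed for the stochastic methods (forests).
#' @param n_trees Trees for the random-forest importances (default 10000).
#' @param k_neighbors ReliefF neighbor count (default 10).
#' @param n_bins Discretization bins for the information-theoretic methods.
#' @return Tibble with columns `feature`, `rank` (1 = most important),
#'   `method`. Ties in method scores are broken by column order.
#' @export
rank_features <- function(X, y,
                          method = c("mRMR", "ReliefF", "InfoGain", "Chi2",
                                     "RF_MDA", "RF_MDG"),
                          seed = 1L, n_trees = 10000L, k_neighbors = 10L,
                          n_bins = 10L) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1)))) abort("all features must be numeric")
  if (anyNA(X)) abort("missing values in features")
  y <- as.character(y)
  if (length(unique(y)) < 2) abort("need two classes to rank features")
  if (min(table(y)) < 2) abort("need >= 2 rows per class")
  p <- ncol(X)
  Xm <- as.matrix(X)

  ord <- switch(method,
    mRMR = mrmr_ranking(Xm, as.integer(factor(y)), n_bins),
    ReliefF = {
      sc <- relieff_scores(Xm, y, k_neighbors)
      order(-sc, seq_len(p))
    },
    InfoGain = {
      B <- matrix(vapply(seq_len(p), function(k) disc_bins(Xm[, k], n_bins),
                         integer(nrow(Xm))), nrow = nrow(Xm))
      sc <- mi_all(as.integer(factor(y)), B)
      order(-sc, seq_len(p))
    },
    Chi2 = {
      B <- matrix(vapply(seq_len(p), function(k) disc_bins(Xm[, k], n_bins),
                         integer(nrow(Xm))), nrow = nrow(Xm))
      sc <- chi2_all(y, B)
      order(-sc, seq_len(p))
    },
    RF_MDA = ,
    RF_MDG = {
      set.seed(seed)
      fit <- randomForest::randomForest(
        x = X, y = factor(y), ntree = n_trees,
        importance = (method == "RF_MDA"))
      imp <- if (method == "RF_MDA")
        randomForest::importance(fit, type = 1)[, 1]
      else
        randomForest::importance(fit, type = 2)[, 1]
      order(-imp, seq_len(p))
    })

  tibble(feature = colnames(X)[ord], rank = seq_len(p), method = method)
}
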