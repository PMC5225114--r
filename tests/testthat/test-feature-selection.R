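test_that("a perfectly separating feature is ranked first by every method", {
  # 100 points, one feature equal to the class indicator, 8 pure-noise columns
  set.seed(10)
  n <- 100
  y <- rep(c("progressive", "responsive"), each = n / 2)
  X <- data.frame(signal = as.numeric(y == "progressive") , check.names = FALSE)
  for (k in 1:8) X[[paste0("noise", k)]] <- rnorm(n)
  for (m in c("mRMR", "ReliefF", "InfoGain", "Chi2", "RF_MDA", "RF_MDG")) {
    r <- rank_features(X, y, method = m, seed = 1, n_trees = 300)
    expect_equal(r$feature[1], "signal", info = m)
    expect_setequal(r$feature, names(X))
    expect_equal(r$rank, seq_len(ncol(X)))
  }
})

test_that("duplicated columns tie and break by column order under InfoGain/Chi2", {
  set.seed(2)
  n <- 60
  y <- rep(c("progressive", "responsive"), each = n / 2)
  x <- rnorm(n) + (y == "progressive")
  X <- data.frame(a = x, b = rnorm(n), a_copy = x)
  for (m in c("InfoGain", "Chi2")) {
    r <- rank_features(X, y, method = m)
    pos <- match(c("a", "a_copy"), r$feature)
    expect_equal(sort(pos), c(min(pos), min(pos) + 1))  # adjacent ranks
    expect_lt(match("a", r$feature), match("a_copy", r$feature))
  }
})

test_that("InfoGain and Chi2 rankings are invariant to row permutation", {
  set.seed(3)
  tbl <- synthetic_feature_table(n_patients = 12, seed = 3)
  X <- tbl[setdiff(names(tbl), c("patient_id", "time_index", "label"))]
  perm <- sample(nrow(X))
  for (m in c("InfoGain", "Chi2")) {
    r1 <- rank_features(X, tbl$label, method = m)
    r2 <- rank_features(X[perm, ], tbl$label[perm], method = m)
    expect_equal(r1$feature, r2$feature)
  }
})

test_that("single-class labels are rejected", {
  X <- data.frame(a = rnorm(10))
  expect_error(rank_features(X, rep("progressive", 10), "InfoGain"), "two classes")
})

test_that("rank-product fusion reproduces its defining examples", {
  r1 <- tibble::tibble(feature = letters[1:12], rank = 1:12)
  # single ranking: its own top 10 in order
  f1 <- rank_product_fuse(list(r1), top_k = 10)
  expect_equal(f1$fused$feature, letters[1:10])
  expect_equal(f1$fused$score, as.numeric(1:10))

  # ranks {1, 4} across two rankings -> geometric mean 2
  r2 <- tibble::tibble(feature = letters[1:12], rank = c(4, 1, 2, 3, 5:12))
  f2 <- rank_product_fuse(list(r1, r2), top_k = 3)
  expect_equal(f2$fused$score[f2$fused$feature == "a"], 2)

  # a feature ranked 1 everywhere scores 1 and leads the fusion
  r3 <- tibble::tibble(feature = letters[1:12], rank = c(1, 3, 2, 4:12))
  f3 <- rank_product_fuse(list(r1, r3), top_k = 5)
  expect_equal(f3$fused$feature[1], "a")
  expect_equal(f3$fused$score[1], 1)

  expect_error(rank_product_fuse(list()), "empty")
})

test_that("fusion is order-invariant and idempotent on identical rankings", {
  set.seed(8)
  feats <- paste0("f", 1:20)
  rk <- function(s) {
    set.seed(s); tibble::tibble(feature = sample(feats), rank = 1:20)
  }
  rs <- lapply(1:5, rk)
  a <- rank_product_fuse(rs)
  b <- rank_product_fuse(rev(rs))
  expect_equal(a$fused, b$fused)
  # k identical rankings: fused top 10 equals the single ranking's top 10
  same <- rank_product_fuse(rep(list(rs[[1]]), 4))
  expect_equal(same$fused$feature, rs[[1]]$feature[1:10])
  # scores bounded by [1, n_features]
  expect_true(all(a$fused$score >= 1 & a$fused$score <= 20))
})

test_that("round-1 LOPOCV produces methods x patients rankings before fusion", {
  tbl <- synthetic_feature_table(n_patients = 5, per_patient = 2, seed = 4)
  rr <- lopocv_rank_round(tbl, methods = c("InfoGain", "Chi2"), seed = 1)
  expect_equal(rr$n_rankings, 2 * 5)
  expect_equal(nrow(dplyr::distinct(rr$rankings[c("fold", "method")])), 10)
  # 2 patients, 1 method -> 2 rankings (both labels inside each patient so
  # each training fold still sees two classes)
  set.seed(5)
  tbl2 <- tibble::tibble(
    patient_id = rep(c("P01", "P02"), each = 4),
    time_index = rep(1:4, 2),
    label = rep(c("progressive", "responsive"), 4),
    f1 = rnorm(8), f2 = rnorm(8))
  rr2 <- lopocv_rank_round(tbl2, methods = "InfoGain", seed = 1)
  expect_equal(rr2$n_rankings, 2)
})

test_that("29 patients and six rankers yield 174 rankings", {
  tbl <- synthetic_feature_table(n_patients = 29, per_patient = 2,
                                 n_noise = 6, seed = 6)
  rr <- lopocv_rank_round(tbl, seed = 1, n_trees = 30)
  expect_equal(rr$n_rankings, 174)
  expect_equal(nrow(rr$fused), 7)      # whole 7-feature universe qualifies
  expect_equal(rr$fused$feature[1], "signal")
})

test_that("the planted T1pc/CBV rim signal reaches the fused top 3", {
  hits <- 0L
  for (s in 1:3) {
    coh <- generate_cohort(tiny_config(seed = s, effect_size = 2,
                                       n_patients = 6, labeled = 18,
                                       ratio = 0.5, grid = c(20, 20, 10)))
    ft <- scale_features(extract_features(coh, "cer_ner",
                                          maps = modality_maps("cmri")))
    rr <- lopocv_rank_round(ft, methods = c("InfoGain", "Chi2", "ReliefF"),
                            seed = s)
    top3 <- rr$fused$feature[1:3]
    if (any(grepl("^(T1pc|CBV)_", top3))) hits <- hits + 1L
  }
  expect_gte(hits, 2)
})
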