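test_that("midrank reproduces the worked tie example and its invariants", {
  expect_equal(midrank(c(0.5, 0.7, 0.7, 0.9)), c(1, 2.5, 2.5, 4))
  expect_equal(midrank(c(2, 5, 9)), c(1, 2, 3))
  expect_equal(midrank(rep(4, 3)), c(2, 2, 2))
  # rank-sum conservation for arbitrary inputs
  set.seed(1)
  for (rep in 1:5) {
    x <- sample(round(runif(17), 2), 17, replace = TRUE)
    expect_equal(sum(midrank(x)), 17 * 18 / 2)
  }
})

test_that("Kruskal-Wallis H matches the closed-form value on separated groups", {
  # groups {1,2,3} and {4,5,6}: H = 12/(6*7) * (6*2^2 + 15*... ) = 27/7
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  # rank invariance: any monotone transform gives the same H
  kw2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
  expect_equal(kw2$statistic, kw$statistic)
  # identical pooled values: degenerate H = 0, p = 1
  kw3 <- kruskal_wallis(list(rep(1, 4), rep(1, 4)))
  expect_equal(kw3$statistic, 0)
  expect_equal(kw3$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  set.seed(20)
  rejections <- 0L
  n_reps <- 2000
  for (r in seq_len(n_reps)) {
    groups <- split(runif(32), rep(1:4, each = 8))
    if (kruskal_wallis(groups)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_reps, 0.03)
  expect_lte(rejections / n_reps, 0.07)
})

test_that("Dunn-Sidak flags well-separated groups and spares identical ones", {
  ph <- dunn_sidak_compare(list(low = 1:10, high = 100:109))
  expect_equal(ph$top_group, "high")
  expect_true(ph$groups$significant_vs_top[ph$groups$group == "low"])

  same <- dunn_sidak_compare(list(a = 1:6, b = 1:6, c = 1:6))
  expect_false(any(same$groups$significant_vs_top))

  # the top group's mean rank is maximal
  set.seed(2)
  ph2 <- dunn_sidak_compare(split(rnorm(40), rep(letters[1:4], 10)))
  top_rank <- ph2$groups$mean_rank[ph2$groups$group == ph2$top_group]
  expect_true(all(ph2$groups$mean_rank <= top_rank))
})

test_that("with one comparison the interval rule matches the unadjusted z test", {
  set.seed(7)
  g <- list(a = rnorm(12), b = rnorm(12) + 1)
  ph <- dunn_sidak_compare(g, alpha = 0.05)
  r <- midrank(unlist(g))
  diff <- abs(mean(r[1:12]) - mean(r[13:24]))
  n <- 24
  se <- sqrt((n * (n + 1) / 12) * (2 / 12))
  flagged <- ph$groups$significant_vs_top[ph$groups$group != ph$top_group]
  expect_equal(flagged, diff > qnorm(0.975) * se)
})

test_that("tidy and glance expose the comparison results", {
  ph <- dunn_sidak_compare(list(a = 1:5, b = 6:10))
  td <- tidy(ph)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("group", "n", "mean_rank", "halfwidth",
                     "significant_vs_top"))
  gl <- glance(ph)
  expect_equal(gl$n_groups, 2)
  expect_equal(gl$top_group, "b")
})

test_that("grouping schemes partition the full 560-cell grid as 56/8/14/20 groups", {
  set.seed(30)
  grid <- tidyr::expand_grid(
    delineation = c("total", "cer_ner"),
    modality = c("cmri", "pwi", "dki", "cpd"),
    classifier = c("LDA", "SVMlin", "SVMrbf", "RF", "AdaBoost", "SGB",
                   "RUSBoost"),
    n_features = 1:10)
  grid$bar <- round(runif(nrow(grid), 0.4, 1), 3)
  expect_equal(nrow(grid), 560)
  gs <- build_groupings(grid)
  sizes <- lapply(gs, function(ph) ph$groups$n)
  expect_equal(length(sizes$delineation_modality_classifier), 56)
  expect_true(all(sizes$delineation_modality_classifier == 10))
  expect_equal(length(sizes$delineation_modality), 8)
  expect_true(all(sizes$delineation_modality == 70))
  expect_equal(length(sizes$delineation_classifier), 14)
  expect_true(all(sizes$delineation_classifier == 40))
  expect_equal(length(sizes$delineation_n_features), 20)
  expect_true(all(sizes$delineation_n_features == 28))
  # group sizes of every scheme sum to the grid size
  for (s in sizes) expect_equal(sum(s), 560)
})

test_that("an incomplete grid is rejected with the missing cells named", {
  grid <- tidyr::expand_grid(delineation = "total", modality = c("cmri", "pwi"),
                             classifier = "LDA", n_features = 1:10)
  grid$bar <- runif(nrow(grid))
  expect_error(build_groupings(grid[-3, ]), "missing cells")
})

test_that("the forest plot of a comparison builds without error", {
  ph <- dunn_sidak_compare(list(a = 1:8, b = 5:12, c = 9:16))
  p <- autoplot(ph)
  expect_s3_class(p, "ggplot")
})
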