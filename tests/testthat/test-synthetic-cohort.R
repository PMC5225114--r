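test_that("identical config and seed reproduce the cohort bit-exactly", {
  cfg <- tiny_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$timepoints[[3]]$maps$CBV, b$timepoints[[3]]$maps$CBV)
  expect_identical(a$timepoints[[1]]$total_mask, b$timepoints[[1]]$total_mask)
})

test_that("default cohort structure gives the 34/21 progressive/responsive split", {
  cfg <- cohort_config(grid_shape = c(20, 20, 10), seed = 2)
  coh <- generate_cohort(cfg)
  lab <- coh$manifest[coh$manifest$label != "unlabeled", ]
  expect_equal(nrow(lab), 55)
  expect_equal(sum(lab$label == "progressive"), 34)
  expect_equal(sum(lab$label == "responsive"), 21)
  expect_equal(length(unique(coh$manifest$patient_id)), 29)
  # one label per patient
  per_pat <- tapply(lab$label, lab$patient_id, function(x) length(unique(x)))
  expect_true(all(per_pat == 1))
})

test_that("masks are disjoint, non-empty, with >= 30 NAWM voxels in every time point", {
  coh <- generate_cohort(tiny_config(seed = 5, n_patients = 3, labeled = 6))
  for (tp in coh$timepoints) {
    expect_true(any(tp$total_mask))
    expect_gte(sum(tp$nawm_mask), 30)
    expect_false(any(tp$total_mask & tp$nawm_mask))
    expect_identical(dim(tp$maps$T1pc), dim(tp$total_mask))
  }
})

test_that("a grid too small for disjoint masks is a configuration error", {
  expect_error(generate_cohort(tiny_config(grid = c(8, 8, 8))), "too small")
})

test_that("effect_size = 0 leaves no class difference in tumor T1pc means", {
  # Monte-Carlo over seeds: per-seed two-sample t-test on per-time-point mean
  # T1pc within Total, progressive vs responsive, at alpha = 0.01.
  rejections <- 0L
  for (s in 1:50) {
    coh <- generate_cohort(tiny_config(seed = s, effect_size = 0,
                                       n_patients = 4, labeled = 12,
                                       n_unlabeled = 0))
    means <- vapply(coh$timepoints,
                    function(tp) mean(tp$maps$T1pc[tp$total_mask]), numeric(1))
    labs <- coh$manifest$label
    pv <- t.test(means[labs == "progressive"],
                 means[labs == "responsive"])$p.value
    rejections <- rejections + (pv < 0.01)
  }
  expect_lte(rejections, 3)
})

test_that("progressive rim elevation scales the T1pc/CBV class gap with effect_size", {
  gap <- function(effect, s) {
    coh <- generate_cohort(tiny_config(seed = s, effect_size = effect,
                                       n_patients = 4, labeled = 8,
                                       n_unlabeled = 0))
    means <- vapply(coh$timepoints,
                    function(tp) mean(tp$maps$T1pc[tp$total_mask]) /
                      mean(tp$maps$T1pc[tp$nawm_mask]), numeric(1))
    labs <- coh$manifest$label
    mean(means[labs == "progressive"]) - mean(means[labs == "responsive"])
  }
  gaps0 <- mean(vapply(1:5, function(s) gap(0, s), numeric(1)))
  gaps2 <- mean(vapply(1:5, function(s) gap(2, s), numeric(1)))
  expect_gt(gaps2, gaps0 + 0.2)
})

test_that("write_cohort emits 18 NIfTI volumes per time point and round-trips", {
  coh <- generate_cohort(tiny_config(seed = 9, n_patients = 2, labeled = 2,
                                     n_unlabeled = 0))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), length(coh$timepoints))
  files_tp1 <- list.files(dir, pattern = "^P01_T01_.*\\.nii\\.gz$")
  expect_length(files_tp1, 18)   # 16 maps + 2 masks
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  back <- read_cohort(dir)
  expect_equal(nrow(back$manifest), nrow(coh$manifest))
  for (k in seq_along(coh$timepoints)) {
    expect_identical(sum(back$timepoints[[k]]$total_mask),
                     sum(coh$timepoints[[k]]$total_mask))
    expect_identical(sum(back$timepoints[[k]]$nawm_mask),
                     sum(coh$timepoints[[k]]$nawm_mask))
    expect_equal(back$timepoints[[k]]$maps$FLAIR, coh$timepoints[[k]]$maps$FLAIR,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # collision without overwrite flag is refused
  expect_error(write_cohort(coh, dir), "overwrite")
  expect_silent(write_cohort(coh, dir, overwrite = TRUE))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(class_ratio = 1.2), "class_ratio")
  expect_error(cohort_config(effect_size = -1), "effect_size")
})
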