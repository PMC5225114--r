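Package: gliorad
Title: Radiomic Classification of Progressive vs. Responsive Glioblastoma Follow-Up MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying follow-up glioblastoma
    multiforme (GBM) time points as progressive or responsive from
    multi-parametric MRI. Includes a synthetic multi-parametric cohort
    generator (16 co-registered parameter maps plus tumor and
    normal-appearing-white-matter masks), percentile-based splitting of the
    tumor region into contrast-enhancing and non-enhancing subregions,
    NAWM-normalized histogram and gray-level co-occurrence (Haralick) texture
    feature extraction, rank-product fusion of six feature rankers under
    leave-one-patient-out cross-validation, balanced-accuracy benchmarking of
    seven classifiers over a delineation by modality by feature-count grid,
    and nonparametric comparison of result groups via Kruskal-Wallis tests
    with Dunn-Sidak post-hoc rank intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    MASS,
    purrr,
    randomForest,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
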