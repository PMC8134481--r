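Package: odordisc
Title: Discriminating Perceptual Odor Properties Between Normosmic and
    Hyposmic Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-arm analysis pipeline identifying which perceptual odor
    properties (edibility, intensity, irritation, temperature, familiarity,
    hedonics, painfulness) and which odors are rated differently by subjects
    with normal versus reduced olfactory function. An unsupervised arm
    projects diagnosis-stratified mean rating profiles by principal component
    analysis and categorizes odors by the paired displacement between
    diagnoses using computed ABC analysis; a supervised arm runs Monte-Carlo
    cross-validated random forests on the sparse block-diagonal subject-by-
    rating matrix, fuses Gini importance with Wilcoxon effect sizes by rank
    products, and selects the most and least diagnosis-relevant odor/property
    cells by ABC analysis in both rank directions. The arms are fused by
    intersection, and the resulting distinctive and non-distinctive odor sets
    are characterized chemically with CATS2D pharmacophore-pair topological
    descriptors and leave-one-out tree-ensemble classification. A synthetic
    cohort generator with controllable planted diagnosis effects reproduces
    the rating-study design (4 odor sets, 10 odors each, 7 properties, two
    ratings per item, 1-5 grades, missingness) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    pROC,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
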