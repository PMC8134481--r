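test_that("completeness filter keeps subjects at or above two thirds", {
  cohort <- simulate_cohort(cohort_design(missing_rate = 0), seed = 8)
  # subject 1: 100/140 present (71.4%) -> kept; subject 2: 90/140 -> dropped
  s1 <- which(cohort$subject_id == "S001")
  s2 <- which(cohort$subject_id == "S002")
  cohort$grade[s1[seq_len(40)]] <- NA
  cohort$grade[s2[seq_len(50)]] <- NA
  filtered <- suppressMessages(filter_complete(cohort))
  expect_true("S001" %in% filtered$subject_id)
  expect_false("S002" %in% filtered$subject_id)
  expect_equal(attr(filtered, "excluded"), "S002")

  complete <- simulate_cohort(cohort_design(missing_rate = 0), seed = 8)
  expect_equal(nrow(filter_complete(complete)), nrow(complete))
})

test_that("imputing a complete cohort is the identity", {
  cohort <- simulate_cohort(tiny_design(), effect_spec(shift = 0), seed = 4)
  imputed <- impute_knn(cohort)
  expect_equal(imputed$grade, as.numeric(cohort$grade))
  expect_identical(imputed[names(imputed) != "grade"],
                   cohort[names(cohort) != "grade"])
})

test_that("three identical neighbors force their shared value", {
  # 5 subjects x 4 slots (2 odors x 2 properties x 1 rep); M01 misses slot 1;
  # M02-M04 agree with M01 on all observed slots and hold 4 there
  grades <- rbind(
    c(NA, 2, 3, 4),
    c(4, 2, 3, 4),
    c(4, 2, 3, 4),
    c(4, 2, 3, 4),
    c(1, 5, 5, 5)
  )
  cohort <- manual_cohort(grades, rep(c("normosmic", "hyposmic"), c(3, 2)),
                          n_odors = 2, n_properties = 2)
  imputed <- impute_knn(cohort, k = 3)
  got <- imputed$grade[imputed$subject_id == "M01" & imputed$odor == "o1" &
                         imputed$property == "p1"]
  expect_equal(got, 4)
})

test_that("imputed values match the brute-force neighbor oracle", {
  set.seed(21)
  for (case in 1:5) {
    grades <- matrix(sample(1:5, 5 * 6, TRUE), nrow = 5)
    grades[1, 2] <- NA
    grades[3, 5] <- NA
    cohort <- manual_cohort(grades, rep(c("normosmic", "hyposmic"), c(3, 2)),
                            n_odors = 3, n_properties = 2)
    imputed <- suppressMessages(impute_knn(cohort, k = 3))
    wide <- matrix(imputed$grade, nrow = 5, byrow = TRUE)
    expect_equal(wide[1, 2], oracle_knn_value(grades, 1, 2, k = 3))
    expect_equal(wide[3, 5], oracle_knn_value(grades, 3, 5, k = 3))
    # observed cells never change
    expect_equal(wide[!is.na(grades)], grades[!is.na(grades)])
  }
})

test_that("too-small odor sets are rejected and sparse slots fall back", {
  grades <- rbind(c(NA, 2), c(3, 2), c(4, 2))
  cohort <- manual_cohort(grades, rep(c("normosmic", "hyposmic"), c(2, 1)),
                          n_odors = 1, n_properties = 2)
  expect_error(impute_knn(cohort, k = 3), class = "odordisc_config_error")
  # k = 2 needs 2 neighbors observing the slot; only 2 exist -> kNN path;
  # with k = 2 but one neighbor missing the slot too, fall back to slot mean
  grades2 <- rbind(c(NA, 2), c(NA, 2), c(4, 2), c(5, 2))
  cohort2 <- manual_cohort(grades2, rep(c("normosmic", "hyposmic"), c(2, 2)),
                           n_odors = 1, n_properties = 2)
  expect_message(impute_knn(cohort2, k = 3), "fell back")
})

test_that("the feature matrix has the block-diagonal study geometry", {
  cohort <- simulate_cohort(cohort_design(missing_rate = 0), seed = 1)
  fm <- build_feature_matrix(cohort)
  info <- attr(fm, "feature_info")
  expect_equal(nrow(fm), 146L)
  expect_equal(nrow(info), 280L)       # 4 x 10 x 7
  expect_equal(ncol(fm), 3L + 280L)
  # in-block cells present, out-of-block structurally absent
  for (s in 1:4) {
    rows <- fm$odor_set == s
    in_block <- as.matrix(fm[rows, info$column[info$odor_set == s]])
    out_block <- as.matrix(fm[rows, info$column[info$odor_set != s]])
    expect_false(anyNA(in_block))
    expect_true(all(is.na(out_block)))
  }
  # repetitions collapse by mean: check one cell by hand
  cell <- cohort |>
    dplyr::filter(subject_id == "S001", odor == cohort$odor[1],
                  property == cohort$property[1])
  expect_equal(fm[[paste(cell$odor[1], cell$property[1], sep = ".")]][
    fm$subject_id == "S001"], mean(cell$grade))
})

test_that("a constant-grade subject fills its whole block with that grade", {
  grades <- matrix(3, nrow = 4, ncol = 4)
  cohort <- manual_cohort(grades, rep(c("normosmic", "hyposmic"), 2),
                          n_odors = 2, n_properties = 2)
  fm <- build_feature_matrix(cohort)
  expect_true(all(as.matrix(fm[, -(1:3)]) == 3))
})

test_that("an odor rated in two sets is a data-integrity error", {
  cohort <- simulate_cohort(tiny_design(), effect_spec(shift = 0), seed = 2)
  cohort$odor[cohort$odor == "set2 odor 01"] <- "set1 odor 01"
  expect_error(build_feature_matrix(cohort), class = "odordisc_data_error")
})

test_that("mean profiles have one row per odor and diagnosis", {
  cohort <- simulate_cohort(cohort_design(missing_rate = 0), seed = 1)
  prof <- build_mean_profiles(cohort)
  expect_equal(nrow(prof), 80L)        # 40 odors x 2 diagnoses
  expect_equal(setdiff(names(prof), c("odor_set", "odor", "diagnosis")),
               odor_properties())
  expect_equal(sum(prof$diagnosis == "hyposmic"), 40L)
  # all means stay within the grade scale
  vals <- as.matrix(prof[, odor_properties()])
  expect_true(all(vals >= 1 & vals <= 5))
})

test_that("mean profiles average exactly and commute with relabeling", {
  grades <- rbind(c(2, 2), c(4, 4), c(2, 4), c(4, 2))
  cohort <- manual_cohort(grades, rep(c("normosmic", "hyposmic"), each = 2),
                          n_odors = 1, n_properties = 2)
  prof <- build_mean_profiles(cohort)
  expect_equal(prof$p1, c(3, 3))
  expect_equal(prof$p2, c(3, 3))

  all_c <- manual_cohort(matrix(2, 4, 4),
                         rep(c("normosmic", "hyposmic"), 2),
                         n_odors = 2, n_properties = 2)
  expect_true(all(as.matrix(build_mean_profiles(all_c)[, c("p1", "p2")]) == 2))

  relabeled <- cohort
  relabeled$subject_id <- sub("M", "Z", relabeled$subject_id)
  expect_equal(build_mean_profiles(relabeled), prof)
})

test_that("a diagnosis absent from a set breaks the profile design", {
  cohort <- simulate_cohort(tiny_design(), effect_spec(shift = 0), seed = 2)
  broken <- dplyr::filter(cohort, !(odor_set == 2 & diagnosis == "hyposmic"))
  expect_error(build_mean_profiles(broken), class = "odordisc_data_error")
})
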