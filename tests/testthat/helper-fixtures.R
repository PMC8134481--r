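# Small in-code fixtures shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_design <- function(...) {
  cohort_design(
    n_sets = 2L, odors_per_set = 3L, n_properties = 2L,
    set_sizes = c(8L, 8L), hyposmic_per_set = c(4L, 4L),
    ratings_per_item = 2L, missing_rate = 0, ...
  )
}

# A hand-built one-set cohort: `grades` is a subjects x (odor x property x
# repetition) matrix in (odor, property, repetition) slot order.
manual_cohort <- function(grades, diagnosis, n_odors, n_properties,
                          n_reps = 1L, odor_set = 1L) {
  n_sub <- nrow(grades)
  slots <- expand.grid(
    repetition = seq_len(n_reps),
    property = sprintf("p%d", seq_len(n_properties)),
    odor = sprintf("o%d", seq_len(n_odors)),
    stringsAsFactors = FALSE
  )[, c("odor", "property", "repetition")]
  stopifnot(ncol(grades) == nrow(slots))
  tibble::tibble(
    subject_id = rep(sprintf("M%02d", seq_len(n_sub)), each = nrow(slots)),
    diagnosis = rep(diagnosis, each = nrow(slots)),
    odor_set = odor_set,
    odor = rep(slots$odor, n_sub),
    property = rep(slots$property, n_sub),
    repetition = rep(slots$repetition, n_sub),
    grade = as.vector(t(grades))
  )
}

# A feature matrix with a single perfectly separating feature: odor o1,
# property p1 is low for normosmic and high for hyposmic subjects.
separable_matrix <- function(n_per_stratum = 4L) {
  design <- cohort_design(
    n_sets = 1L, odors_per_set = 2L, n_properties = 2L,
    set_sizes = 2L * n_per_stratum, hyposmic_per_set = n_per_stratum,
    missing_rate = 0
  )
  cohort <- simulate_cohort(design, effect_spec(shift = 0), seed = 99)
  cohort$grade <- 3L
  sep <- cohort$odor == "set1 odor 01" & cohort$property == "property01"
  cohort$grade[sep] <- ifelse(cohort$diagnosis[sep] == "hyposmic", 5L, 1L)
  build_feature_matrix(cohort)
}

relevance_from_matrices <- function(importance, neglogp, info) {
  structure(
    list(
      relevance = dplyr::mutate(info, importance_mean = importance,
                                neglogp_mean = neglogp),
      auc = tibble::tibble(run = 1L, auc = 0.5),
      config = run_config(n_runs = 1L),
      permuted = FALSE
    ),
    class = "relevance_result"
  )
}

toy_info <- function(n_odors = 8L, n_props = 3L) {
  tidyr::expand_grid(
    odor_set = 1L,
    odor = sprintf("o%02d", seq_len(n_odors)),
    property = sprintf("p%d", seq_len(n_props))
  )
}
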