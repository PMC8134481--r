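#' Filter subjects by rating completeness
#'
#' Keeps subjects who completed at least `min_fraction` of their required
#' ratings (by default two thirds of the odors-by-properties-by-repetitions
#' slots of their own odor set).
#'
#' @param cohort A rating cohort tibble.
#' @param min_fraction Minimum non-missing fraction per subject, in (0, 1].
#' @return The filtered cohort; excluded subject ids are attached as
#'   attribute `"excluded"` and reported via a message.
#' @export
filter_complete <- function(cohort, min_fraction = 2 / 3) {
  check_cohort(cohort)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (nrow(cohort) == 0) {
    warn("empty cohort; nothing to filter")
    return(structure(cohort, excluded = character()))
  }
  completeness <- cohort |>
    group_by(.data$subject_id) |>
    summarise(frac = mean(!is.na(.data$grade)), .groups = "drop")
  excluded <- completeness$subject_id[completeness$frac < min_fraction]
  if (length(excluded)) {
    inform(sprintf("excluding %d subject(s) below %.1f%% completeness: %s",
                   length(excluded), 100 * min_fraction,
                   paste(excluded, collapse = ", ")))
  }
  out <- filter(cohort, !.data$subject_id %in% excluded)
  structure(out, excluded = excluded)
}

#' Impute missing ratings by k-nearest neighbors within odor set
#'
#' Fills each subject's missing rating slots from the `k` most similar
#' subjects of the same odor set.  Similarity is the root-mean-square
#' difference over mutually observed slots (so sparser overlaps are not
#' spuriously close), and the imputed value is the exp(-distance)-weighted
#' mean of the neighbors' observed values for that slot.  Observed ratings
#' are never altered.  When fewer than `k` neighbors observe a slot (or
#' share no rated slot with the subject), the within-set slot mean is used
#' instead and a message is emitted.
#'
#' @param cohort A (typically completeness-filtered) rating cohort.
#' @param k Number of neighbors.
#' @return The cohort with no missing grades; imputed values are real-valued
#'   means, not re-rounded to grades.
#' @export
impute_knn <- function(cohort, k = 3L) {
  check_cohort(cohort)
  stopifnot(k >= 1L)
  if (!anyNA(cohort$grade)) {
    return(mutate(cohort, grade = as.numeric(.data$grade)))
  }
  slot_id <- function(d) paste(d$odor, d$property, d$repetition, sep = "\r")
  out <- cohort |> mutate(grade = as.numeric(.data$grade))
  fallbacks <- 0L

  for (s in sort(unique(out$odor_set))) {
    idx <- which(out$odor_set == s)
    block <- out[idx, ]
    wide <- block |>
      mutate(slot = slot_id(block)) |>
      select("subject_id", "slot", "grade") |>
      tidyr::pivot_wider(names_from = "slot", values_from = "grade")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$subject_id
    if (!anyNA(m)) next
    if (nrow(m) < k + 1L) {
      abort(sprintf("odor set %d has %d subjects; need at least k+1 = %d",
                    s, nrow(m), k + 1L),
            class = "odordisc_config_error")
    }
    col_means <- colMeans(m, na.rm = TRUE)
    filled <- m
    for (i in which(rowSums(is.na(m)) > 0)) {
      diffs <- sweep(m[-i, , drop = FALSE], 2, m[i, ])
      overlap <- rowSums(!is.na(diffs))
      d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / overlap)
      for (j in which(is.na(m[i, ]))) {
        cand <- which(overlap > 0 & !is.na(m[-i, j]))
        if (length(cand) < k) {
          filled[i, j] <- col_means[j]
          fallbacks <- fallbacks + 1L
          next
        }
        nearest <- cand[order(d[cand])][seq_len(k)]
        w <- exp(-d[nearest])
        if (sum(w) == 0) w <- rep(1, k)
        filled[i, j] <- sum(w * m[-i, , drop = FALSE][nearest, j]) / sum(w)
      }
    }
    long <- tibble(
      subject_id = rep(rownames(filled), times = ncol(filled)),
      slot = rep(colnames(filled), each = nrow(filled)),
      imputed = as.vector(filled)
    )
    key <- paste(out$subject_id[idx], slot_id(block), sep = "\r")
    out$grade[idx] <- long$imputed[match(key, paste(long$subject_id, long$slot,
                                                    sep = "\r"))]
  }
  if (fallbacks > 0) {
    inform(sprintf(
      "kNN imputation fell back to the slot mean for %d cell(s)", fallbacks))
  }
  if (anyNA(out$grade)) {
    abort("imputation left missing grades", class = "odordisc_data_error")
  }
  out
}

#' Build the subject-by-rating feature matrix
#'
#' Collapses the two repeat ratings by arithmetic mean and spreads the
#' cohort to one row per subject and one column per (odor set, odor,
#' property) triple.  Subjects only rate their own odor set, so the matrix
#' is sparse block-diagonal: cells outside a subject's set are structurally
#' absent (`NA`), not zero.  For the default design this is the 146 x 280
#' matrix the supervised arm classifies.
#'
#' @param cohort An imputed rating cohort.
#' @return A tibble with columns `subject_id`, `diagnosis`, `odor_set`
#'   followed by one numeric column per feature, named `odor.property`.
#'   Attribute `"feature_info"` maps columns to (odor_set, odor, property)
#'   in deterministic (set, odor, property) order.
#' @export
build_feature_matrix <- function(cohort) {
  check_cohort(cohort)
  catalog <- cohort |>
    distinct(.data$odor_set, .data$odor) |>
    arrange(.data$odor_set, .data$odor)
  bad <- cohort |>
    distinct(.data$subject_id, .data$odor_set, .data$odor) |>
    group_by(.data$odor) |>
    summarise(n_sets = n_distinct(.data$odor_set), .groups = "drop") |>
    filter(.data$n_sets > 1L)
  if (nrow(bad)) {
    abort(paste("odor(s) rated in more than one set:",
                paste(bad$odor, collapse = ", ")),
          class = "odordisc_data_error")
  }
  props <- unique(cohort$property)
  if (all(odor_properties() %in% props)) {
    props <- odor_properties()[odor_properties() %in% props]
  } else {
    props <- sort(props)
  }
  feature_info <- catalog |>
    tidyr::expand_grid(property = props) |>
    arrange(.data$odor_set, .data$odor,
            match(.data$property, props)) |>
    mutate(column = paste(.data$odor, .data$property, sep = "."))

  cells <- cohort |>
    group_by(.data$subject_id, .data$diagnosis, .data$odor_set, .data$odor,
             .data$property) |>
    summarise(value = mean(.data$grade), .groups = "drop") |>
    mutate(column = paste(.data$odor, .data$property, sep = "."))
  wide <- cells |>
    select("subject_id", "diagnosis", "odor_set", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  ordered_cols <- c("subject_id", "diagnosis", "odor_set", feature_info$column)
  absent <- setdiff(feature_info$column, names(wide))
  for (colname in absent) wide[[colname]] <- NA_real_
  out <- wide[, ordered_cols] |> arrange(.data$subject_id)
  structure(out, feature_info = feature_info)
}

#' Build diagnosis-stratified mean odor profiles
#'
#' Averages grades over all subjects of each diagnosis within an odor's set
#' (and over both repeat ratings), producing one row per (odor, diagnosis)
#' pair and one column per property -- the 80 x 7 matrix the unsupervised
#' arm projects.
#'
#' @param cohort An imputed rating cohort.
#' @return A tibble with columns `odor_set`, `odor`, `diagnosis` and one
#'   numeric column per property.
#' @export
build_mean_profiles <- function(cohort) {
  check_cohort(cohort)
  present <- cohort |>
    distinct(.data$odor_set, .data$diagnosis) |>
    count(.data$odor_set)
  if (any(present$n < 2L)) {
    abort(sprintf("odor set(s) %s lack one of the two diagnoses",
                  paste(present$odor_set[present$n < 2L], collapse = ", ")),
          class = "odordisc_data_error")
  }
  props <- unique(cohort$property)
  if (all(odor_properties() %in% props)) {
    props <- odor_properties()[odor_properties() %in% props]
  } else {
    props <- sort(props)
  }
  cohort |>
    group_by(.data$odor_set, .data$odor, .data$diagnosis, .data$property) |>
    summarise(value = mean(.data$grade, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "property", values_from = "value") |>
    select(dplyr::all_of(c("odor_set", "odor", "diagnosis", props))) |>
    arrange(.data$odor_set, .data$odor, .data$diagnosis)
}
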