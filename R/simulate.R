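#' Simulate a rating cohort
#'
#' Draws a complete long-format cohort of odor-property ratings under a
#' latent Gaussian model.  Each odor-property item has a baseline mean drawn
#' uniformly from the middle of the grade scale; a subject's latent rating
#' adds the planted diagnosis shift (for hyposmic subjects on affected
#' items) and Gaussian noise, and is then rounded and clipped to the grade
#' scale.  Missing ratings are inserted uniformly at random within each
#' subject at the design's `missing_rate`.
#'
#' @param design A [cohort_design()].
#' @param effect An [effect_spec()].
#' @param seed Integer seed; overrides `design$seed` when given.  With a
#'   seed, identical calls yield identical cohorts.
#' @return A tibble with one row per rating slot and columns `subject_id`,
#'   `diagnosis` (`"normosmic"`/`"hyposmic"`), `odor_set`, `odor`,
#'   `property`, `repetition` and `grade` (integer, `NA` = missing).
#' @examples
#' cohort <- simulate_cohort(cohort_design(missing_rate = 0), seed = 1)
#' dplyr::count(cohort, diagnosis)
#' @export
simulate_cohort <- function(design = cohort_design(),
                            effect = effect_spec(),
                            seed = NULL) {
  stopifnot(inherits(design, "cohort_design"), inherits(effect, "effect_spec"))
  validate_cohort_design(design)
  seed <- seed %||% design$seed
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_cohort_impl(design, effect)))
  }
  simulate_cohort_impl(design, effect)
}

simulate_cohort_impl <- function(design, effect) {
  catalog <- odor_catalog(design)
  props <- if (design$n_properties == 7L) odor_properties() else
    sprintf("property%02d", seq_len(design$n_properties))
  unknown <- setdiff(effect$affected_properties, props)
  if (length(unknown) && effect$shift != 0) {
    warn(paste("affected properties not in the design:",
               paste(unknown, collapse = ", ")))
  }
  if (!is.null(effect$affected_odors)) {
    missing_odors <- setdiff(effect$affected_odors, catalog$odor)
    if (length(missing_odors)) {
      abort(paste("affected odors not in the catalog:",
                  paste(missing_odors, collapse = ", ")),
            class = "odordisc_config_error")
    }
  }

  lo <- design$rating_scale[1]
  hi <- design$rating_scale[2]
  mid <- (lo + hi) / 2
  # item baselines: uniform over the central half of the scale, so planted
  # shifts of +-1 grade rarely saturate at the scale ends
  baselines <- catalog |>
    tidyr::expand_grid(property = props) |>
    mutate(baseline = runif(dplyr::n(), mid - (hi - lo) / 4,
                            mid + (hi - lo) / 4))

  subjects <- purrr::map_dfr(seq_len(design$n_sets), function(s) {
    n_s <- design$set_sizes[s]
    n_h <- design$hyposmic_per_set[s]
    tibble(
      odor_set = s,
      diagnosis = c(rep("hyposmic", n_h), rep("normosmic", n_s - n_h))
    )
  })
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))

  cohort <- subjects |>
    left_join(baselines, by = "odor_set", relationship = "many-to-many") |>
    tidyr::expand_grid(repetition = seq_len(design$ratings_per_item))

  affected <- cohort$diagnosis == "hyposmic" &
    cohort$property %in% effect$affected_properties &
    (is.null(effect$affected_odors) | cohort$odor %in% (effect$affected_odors %||% ""))
  latent <- cohort$baseline + effect$shift * affected +
    rnorm(nrow(cohort), sd = effect$noise_sd)
  cohort$grade <- as.integer(pmin(hi, pmax(lo, round(latent))))

  if (design$missing_rate > 0) {
    per_subject <- design$odors_per_set * design$n_properties *
      design$ratings_per_item
    n_miss <- round(design$missing_rate * per_subject)
    if (n_miss > 0) {
      drop <- cohort |>
        mutate(.row = row_number()) |>
        group_by(.data$subject_id) |>
        dplyr::slice_sample(n = n_miss) |>
        pull(.data$.row)
      cohort$grade[drop] <- NA_integer_
    }
  }

  cohort |>
    select("subject_id", "diagnosis", "odor_set", "odor", "property",
           "repetition", "grade") |>
    arrange(.data$subject_id, .data$odor_set, .data$odor, .data$property,
            .data$repetition)
}

#' Write / read a rating cohort as CSV
#'
#' Long-format CSV with columns
#' `subject_id,diagnosis,odor_set,odor,property,repetition,grade`; an empty
#' `grade` cell marks a missing rating.  The round trip is lossless.
#'
#' @param cohort A cohort tibble as from [simulate_cohort()].
#' @param path File path.
#' @return `cohort_to_csv()` returns `path` invisibly; `csv_to_cohort()`
#'   returns the cohort tibble.
#' @export
cohort_to_csv <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param rating_scale Inclusive grade bounds used to validate parsed grades.
#' @rdname cohort_to_csv
#' @export
csv_to_cohort <- function(path, rating_scale = c(1L, 5L)) {
  raw <- read.csv(path, colClasses = "character")
  needed <- c("subject_id", "diagnosis", "odor_set", "odor", "property",
              "repetition", "grade")
  if (!identical(names(raw), needed)) {
    abort(sprintf("malformed cohort file %s: expected columns %s", path,
                  paste(needed, collapse = ",")),
          class = "odordisc_parse_error")
  }
  parse_int <- function(x, what) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & x != "")
    if (length(bad)) {
      abort(sprintf("line %d of %s: unreadable %s '%s'",
                    bad[1] + 1L, path, what, x[bad[1]]),
            class = "odordisc_parse_error")
    }
    out
  }
  grade <- parse_int(raw$grade, "grade")
  out_of_scale <- which(!is.na(grade) &
                          (grade < rating_scale[1] | grade > rating_scale[2]))
  if (length(out_of_scale)) {
    abort(sprintf("line %d of %s: grade %d outside scale [%d, %d]",
                  out_of_scale[1] + 1L, path, grade[out_of_scale[1]],
                  rating_scale[1], rating_scale[2]),
          class = "odordisc_parse_error")
  }
  bad_diag <- which(!raw$diagnosis %in% c("normosmic", "hyposmic"))
  if (length(bad_diag)) {
    abort(sprintf("line %d of %s: unknown diagnosis '%s'",
                  bad_diag[1] + 1L, path, raw$diagnosis[bad_diag[1]]),
          class = "odordisc_parse_error")
  }
  tibble(
    subject_id = raw$subject_id,
    diagnosis = raw$diagnosis,
    odor_set = parse_int(raw$odor_set, "odor_set"),
    odor = raw$odor,
    property = raw$property,
    repetition = parse_int(raw$repetition, "repetition"),
    grade = grade
  )
}

check_cohort <- function(cohort) {
  needed <- c("subject_id", "diagnosis", "odor_set", "odor", "property",
              "repetition", "grade")
  if (!all(needed %in% names(cohort))) {
    abort(paste("not a rating cohort; missing columns:",
                paste(setdiff(needed, names(cohort)), collapse = ", ")),
          class = "odordisc_data_error")
  }
  one_each <- cohort |>
    group_by(.data$subject_id) |>
    summarise(ok = n_distinct(.data$diagnosis) == 1L &&
                n_distinct(.data$odor_set) == 1L, .groups = "drop")
  if (!all(one_each$ok)) {
    abort("each subject must have exactly one diagnosis and one odor set",
          class = "odordisc_data_error")
  }
  invisible(cohort)
}
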