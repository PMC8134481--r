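#' Describe the rating-study design
#'
#' Captures the dimensions of the rating experiment: how many odor test sets
#' there are, how many odors and rated properties per set, how many subjects
#' (and how many hyposmic subjects) take each set, how many repeat ratings
#' each subject gives per odor-property item, the grade scale, and the
#' fraction of ratings left missing.  The defaults reproduce the study
#' conditions: 146 subjects over 4 sets (38/33/42/33, of whom 8/9/17/8 are
#' hyposmic), 10 odors per set, 7 properties, 2 ratings per item, grades
#' 1-5.
#'
#' @param n_sets Number of odor test sets.
#' @param odors_per_set Odors in each set.
#' @param n_properties Rated perceptual properties per odor. When 7, the
#'   canonical property names of [odor_properties()] are used.
#' @param set_sizes Integer vector: subjects assigned to each set.
#' @param hyposmic_per_set Integer vector: hyposmic subjects within each set.
#' @param ratings_per_item Repeat ratings per subject, odor and property.
#' @param rating_scale Length-2 integer vector, inclusive grade bounds.
#' @param missing_rate Fraction of each subject's rating slots left missing,
#'   in `[0, 1)`.
#' @param seed Integer seed used by [simulate_cohort()]; `NULL` to use the
#'   current RNG state.
#' @return A `cohort_design` list.
#' @examples
#' cohort_design()
#' @export
cohort_design <- function(n_sets = 4L,
                          odors_per_set = 10L,
                          n_properties = 7L,
                          set_sizes = c(38L, 33L, 42L, 33L),
                          hyposmic_per_set = c(8L, 9L, 17L, 8L),
                          ratings_per_item = 2L,
                          rating_scale = c(1L, 5L),
                          missing_rate = 0.05,
                          seed = NULL) {
  design <- structure(
    list(
      n_sets = as.integer(n_sets),
      odors_per_set = as.integer(odors_per_set),
      n_properties = as.integer(n_properties),
      set_sizes = as.integer(set_sizes),
      hyposmic_per_set = as.integer(hyposmic_per_set),
      ratings_per_item = as.integer(ratings_per_item),
      rating_scale = as.integer(rating_scale),
      missing_rate = missing_rate,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "cohort_design"
  )
  validate_cohort_design(design)
}

validate_cohort_design <- function(design) {
  with(design, {
    if (n_sets < 1L || odors_per_set < 1L || n_properties < 1L ||
        ratings_per_item < 1L) {
      abort("counts in a cohort design must be positive",
            class = "odordisc_config_error")
    }
    if (length(set_sizes) != n_sets || length(hyposmic_per_set) != n_sets) {
      abort("`set_sizes` and `hyposmic_per_set` must have one entry per set",
            class = "odordisc_config_error")
    }
    if (any(set_sizes < 1L) || any(hyposmic_per_set < 0L)) {
      abort("set sizes must be positive and hyposmic counts non-negative",
            class = "odordisc_config_error")
    }
    if (any(hyposmic_per_set > set_sizes)) {
      abort("hyposmic count exceeds set size",
            class = "odordisc_config_error")
    }
    if (length(rating_scale) != 2L || rating_scale[1] >= rating_scale[2]) {
      abort("`rating_scale` must be increasing inclusive bounds",
            class = "odordisc_config_error")
    }
    if (missing_rate < 0 || missing_rate >= 1) {
      abort("`missing_rate` must lie in [0, 1)",
            class = "odordisc_config_error")
    }
  })
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat(sprintf("  %d sets x %d odors x %d properties x %d ratings (grades %d-%d)\n",
              x$n_sets, x$odors_per_set, x$n_properties, x$ratings_per_item,
              x$rating_scale[1], x$rating_scale[2]))
  cat(sprintf("  subjects per set: %s (hyposmic: %s)\n",
              paste(x$set_sizes, collapse = "/"),
              paste(x$hyposmic_per_set, collapse = "/")))
  cat(sprintf("  missing rate: %.3f\n", x$missing_rate))
  invisible(x)
}

#' Specify a planted diagnosis effect
#'
#' Describes how hyposmic subjects' latent ratings differ from normosmic
#' subjects' in a simulated cohort.  The default plants the effect the
#' analysis is meant to recover: familiarity and intensity are rated lower
#' (shift -1 grade) by hyposmic subjects, across all odors.
#'
#' @param affected_properties Properties carrying the diagnosis shift.
#' @param affected_odors Odor names carrying the shift; `NULL` means all.
#' @param shift Mean latent-rating difference (hyposmic minus normosmic), in
#'   grade units.  `shift = 0` gives the null model: the two diagnosis
#'   groups are exchangeable.
#' @param noise_sd Standard deviation of the latent rating noise, in grade
#'   units.
#' @return An `effect_spec` list.
#' @examples
#' effect_spec(shift = 0)           # null model
#' effect_spec(shift = -1)          # the default planted effect
#' @export
effect_spec <- function(affected_properties = c("familiarity", "intensity"),
                        affected_odors = NULL,
                        shift = -1,
                        noise_sd = 1) {
  if (noise_sd <= 0) {
    abort("`noise_sd` must be positive", class = "odordisc_config_error")
  }
  structure(
    list(
      affected_properties = as.character(affected_properties),
      affected_odors = if (!is.null(affected_odors)) as.character(affected_odors),
      shift = shift,
      noise_sd = noise_sd
    ),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>\n")
  cat(sprintf("  shift %+.2f grades on %s\n", x$shift,
              paste(x$affected_properties, collapse = ", ")))
  cat(sprintf("  odors: %s; noise sd %.2f\n",
              if (is.null(x$affected_odors)) "all"
              else paste(x$affected_odors, collapse = ", "),
              x$noise_sd))
  invisible(x)
}
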