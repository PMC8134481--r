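#' Odors exclusive to one rank-product direction
#'
#' From a supervised [rank_product_select()] result, the odors that appear
#' only among the most-relevant cells (exclusively discriminating between
#' diagnoses) and those that appear only among the least-relevant cells
#' (exclusively non-distinguishing).  Odors with cells in both directions
#' are dropped.
#'
#' @param sel A `selection_result`.
#' @return A list with character vectors `exclusive_distinctive` and
#'   `exclusive_nondistinctive`.
#' @export
exclusive_sets <- function(sel) {
  stopifnot(inherits(sel, "selection_result"))
  most <- unique(sel$most_relevant$odor)
  least <- unique(sel$least_relevant$odor)
  list(
    exclusive_distinctive = setdiff(most, least),
    exclusive_nondistinctive = setdiff(least, most)
  )
}

#' Intersect the supervised and unsupervised arms
#'
#' The final odor sets: an odor is distinctive only if the supervised arm
#' found it exclusively discriminating AND the unsupervised projection
#' placed it among the largest paired displacements (and symmetrically for
#' non-distinctive).  Per direction, the overlap fraction reports how many
#' of the supervised-exclusive odors the unsupervised arm confirmed.
#'
#' @param excl Output of [exclusive_sets()].
#' @param categories Output of [categorize_odors()] (the unsupervised arm),
#'   computed on the same odor universe.
#' @return An object of class `consensus_result` with `distinctive_final`,
#'   `nondistinctive_final`, the supervised-exclusive input sets, and
#'   `overlap_fractions` (named numeric; `NA` when a supervised-exclusive
#'   set is empty).
#' @export
intersect_arms <- function(excl, categories) {
  stopifnot(is.list(excl),
            all(c("exclusive_distinctive", "exclusive_nondistinctive") %in%
                  names(excl)))
  universe <- categories$odor
  outside <- setdiff(c(excl$exclusive_distinctive,
                       excl$exclusive_nondistinctive), universe)
  if (length(outside)) {
    abort(paste("supervised odors missing from the unsupervised universe:",
                paste(outside, collapse = ", ")),
          class = "odordisc_data_error")
  }
  unsup_dist <- odor_category(categories, "distinctive")
  unsup_non <- odor_category(categories, "nondistinctive")
  dist_final <- intersect(excl$exclusive_distinctive, unsup_dist)
  non_final <- intersect(excl$exclusive_nondistinctive, unsup_non)
  frac <- function(final, sup) {
    if (length(sup) == 0) NA_real_ else length(final) / length(sup)
  }
  structure(
    list(
      distinctive_final = dist_final,
      nondistinctive_final = non_final,
      supervised_exclusive_distinctive = excl$exclusive_distinctive,
      supervised_exclusive_nondistinctive = excl$exclusive_nondistinctive,
      overlap_fractions = c(
        distinctive = frac(dist_final, excl$exclusive_distinctive),
        nondistinctive = frac(non_final, excl$exclusive_nondistinctive)
      )
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d distinctive / %d non-distinctive odors\n",
              length(x$distinctive_final), length(x$nondistinctive_final)))
  cat("  distinctive:", paste(x$distinctive_final, collapse = ", "), "\n")
  cat("  non-distinctive:", paste(x$nondistinctive_final, collapse = ", "), "\n")
  cat(sprintf("  unsupervised confirmation: %.1f%% / %.1f%%\n",
              100 * x$overlap_fractions["distinctive"],
              100 * x$overlap_fractions["nondistinctive"]))
  invisible(x)
}

#' @rdname intersect_arms
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  bind_rows(
    tibble(odor = x$distinctive_final, status = "distinctive"),
    tibble(odor = x$nondistinctive_final, status = "nondistinctive")
  )
}

#' Hypergeometric enrichment of a final odor set for planted odors
#'
#' For synthetic cohorts with effects planted on a known odor subset:
#' one-sided hypergeometric probability of observing at least the attained
#' overlap between a final odor set and the planted set, drawing
#' `|final set|` odors from the universe.
#'
#' @param final Character vector, e.g. `distinctive_final`.
#' @param planted Character vector of odors carrying the planted effect.
#' @param universe All odors under analysis.
#' @return A one-sided p-value (`NA` if the final set is empty).
#' @export
planted_enrichment <- function(final, planted, universe) {
  if (length(final) == 0) return(NA_real_)
  k <- length(intersect(final, planted))
  phyper(k - 1, length(planted), length(universe) - length(planted),
         length(final), lower.tail = FALSE)
}

#' Write a consensus result as JSON
#'
#' @param x A `consensus_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
consensus_to_json <- function(x, path) {
  stopifnot(inherits(x, "consensus_result"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("consensus_to_json() needs the jsonlite package")
  }
  jsonlite::write_json(unclass(x), path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}
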