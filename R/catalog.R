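#' The seven rated perceptual properties
#'
#' Property names used throughout the pipeline, in their canonical column
#' order: edibility, intensity, irritation, temperature, familiarity,
#' hedonics, painfulness.
#'
#' @return Character vector of length 7.
#' @export
odor_properties <- function() {
  c("edibility", "intensity", "irritation", "temperature",
    "familiarity", "hedonics", "painfulness")
}

# The 40 odorants of the four test sets (10 per set).  Names are kept
# human-readable so result tables read like the study's own.
.odor_names <- list(
  set1 = c("isoamyl acetate", "cineole", "geraniol", "methyl salicylate",
           "trans-anethole", "ethyl acetate", "propionic acid", "eugenol",
           "2-nonanone", "indole"),
  set2 = c("benzaldehyde", "butyric acid", "p-cresol", "guaiacol",
           "linalool", "fenchone", "HMHA", "amyl caproate",
           "2,3-butanedione", "citronellal"),
  set3 = c("cis-3-hexenol", "1-butanol", "4-ethyloctanoic acid",
           "beta-ionone", "2-methylpropanal", "terpinen-4-ol",
           "isobutyric acid", "4-decanolide", "citronellol",
           "3-methyl-3-sulfanylhexan-1-ol"),
  set4 = c("D-limonene", "alpha-pinene", "methional", "benzyl acetate",
           "1-octen-3-ol", "trans-2-hexenyl acetate", "L-carvone",
           "beta-caryophyllene", "heptanal", "2-butanone")
)

#' Catalog of the default odorants
#'
#' The default odor panel: 40 odorants split into four test sets of 10.
#' Each study participant rates only the odors of their assigned set, which
#' is what makes the subject-by-rating feature matrix block-diagonal.
#'
#' @param design A [cohort_design()]. For non-default designs, generic odor
#'   names (`"set2 odor 03"`, ...) are generated instead.
#' @return A tibble with columns `odor_set` (integer) and `odor` (character).
#' @examples
#' odor_catalog()
#' @export
odor_catalog <- function(design = cohort_design()) {
  if (design$n_sets == 4L && design$odors_per_set == 10L) {
    return(tibble(
      odor_set = rep(1:4, each = 10L),
      odor = unlist(.odor_names, use.names = FALSE)
    ))
  }
  tibble(
    odor_set = rep(seq_len(design$n_sets), each = design$odors_per_set),
    odor = sprintf("set%d odor %02d",
                   rep(seq_len(design$n_sets), each = design$odors_per_set),
                   rep(seq_len(design$odors_per_set), design$n_sets))
  )
}
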