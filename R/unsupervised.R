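#' Project mean odor profiles by principal component analysis
#'
#' Centers (but does not scale) the property columns of the
#' diagnosis-stratified mean-profile matrix and decomposes it into
#' principal components.  Besides scores and loadings it reports the
#' fraction of total variance explained by each component and each
#' property's percentage contribution (squared loading, normalized per
#' component).  Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param profiles A mean-profile tibble from [build_mean_profiles()].
#' @param n_components Number of components retained for downstream paired
#'   distances (all components are computed and reported).
#' @return An object of class `odor_projection` with tibbles `scores`
#'   (odor_set, odor, diagnosis, PC1...), `loadings` (property x component),
#'   `variance` (component, sd, variance_fraction) and `contributions`
#'   (property x component, percent per component summing to 100).
#' @export
project_profiles <- function(profiles, n_components = 2L) {
  props <- setdiff(names(profiles), c("odor_set", "odor", "diagnosis"))
  if (!length(props)) {
    abort("no property columns found", class = "odordisc_data_error")
  }
  stopifnot(n_components >= 1L, n_components <= length(props))
  m <- as.matrix(profiles[, props])
  degenerate <- props[apply(m, 2, function(x) var(x) == 0)]
  if (all(apply(m, 2, var) == 0)) {
    abort(paste("all property columns are constant:",
                paste(degenerate, collapse = ", ")),
          class = "odordisc_domain_error")
  }
  pca <- prcomp(m, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading positive
  flip <- apply(pca$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pca$rotation <- sweep(pca$rotation, 2, flip, `*`)
  pca$x <- sweep(pca$x, 2, flip, `*`)

  var_frac <- pca$sdev^2 / sum(pca$sdev^2)
  comp <- colnames(pca$rotation)
  contributions <- sweep(pca$rotation^2, 2, colSums(pca$rotation^2), `/`) * 100

  structure(
    list(
      scores = dplyr::bind_cols(
        profiles[, intersect(c("odor_set", "odor", "diagnosis"),
                             names(profiles))],
        as_tibble(pca$x)
      ),
      loadings = as_tibble(pca$rotation) |>
        mutate(property = props, .before = 1),
      variance = tibble(component = comp, sd = pca$sdev,
                        variance_fraction = var_frac),
      contributions = as_tibble(contributions) |>
        mutate(property = props, .before = 1),
      n_components = as.integer(n_components)
    ),
    class = "odor_projection"
  )
}

#' @export
print.odor_projection <- function(x, ...) {
  cat(sprintf("<odor_projection> %d profiles x %d components; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), nrow(x$variance),
              100 * sum(x$variance$variance_fraction[1:min(2, nrow(x$variance))])))
  invisible(x)
}

#' @rdname project_profiles
#' @param x,object An `odor_projection`.
#' @param ... Unused.
#' @method tidy odor_projection
#' @export
tidy.odor_projection <- function(x, ...) {
  x$loadings |>
    tidyr::pivot_longer(-"property", names_to = "component",
                        values_to = "loading") |>
    left_join(
      x$contributions |>
        tidyr::pivot_longer(-"property", names_to = "component",
                            values_to = "contribution_pct"),
      by = c("property", "component")
    )
}

#' @rdname project_profiles
#' @method glance odor_projection
#' @export
glance.odor_projection <- function(x, ...) {
  tibble(
    n_profiles = nrow(x$scores),
    n_components = nrow(x$variance),
    retained_components = x$n_components,
    retained_variance_fraction =
      sum(x$variance$variance_fraction[seq_len(x$n_components)])
  )
}

#' @rdname project_profiles
#' @method autoplot odor_projection
#' @export
autoplot.odor_projection <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$diagnosis)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$odor), colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
}

#' Paired odor displacement between diagnoses
#'
#' For each odor, the Euclidean distance between its normosmic and hyposmic
#' mean-profile projections on the plane of the retained components -- the
#' arrow length in the projection plot.  Odors whose perception changes
#' with olfactory loss move far; odors perceived alike stay put.
#'
#' @param proj An `odor_projection`.
#' @param components Number of leading components used; defaults to the
#'   projection's retained count (the PC1 x PC2 plane).  Set to the number
#'   of properties for full-space distances.
#' @return A tibble with `odor_set`, `odor` and `distance`, sorted by
#'   decreasing distance.
#' @export
paired_distances <- function(proj, components = NULL) {
  stopifnot(inherits(proj, "odor_projection"))
  components <- components %||% proj$n_components
  pcs <- paste0("PC", seq_len(components))
  counts <- proj$scores |> count(.data$odor)
  if (any(counts$n != 2L)) {
    abort(paste("odor(s) without exactly one profile per diagnosis:",
                paste(counts$odor[counts$n != 2L], collapse = ", ")),
          class = "odordisc_data_error")
  }
  proj$scores |>
    select(dplyr::all_of(c("odor_set", "odor", "diagnosis", pcs))) |>
    tidyr::pivot_longer(dplyr::all_of(pcs), names_to = "component") |>
    tidyr::pivot_wider(names_from = "diagnosis", values_from = "value") |>
    group_by(.data$odor_set, .data$odor) |>
    summarise(distance = sqrt(sum((.data$normosmic - .data$hyposmic)^2)),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$distance))
}

#' Categorize odors by their paired displacement
#'
#' Runs computed ABC analysis on the paired diagnosis distances: set A
#' (largest displacements) are the distinctive odors, set C the
#' non-distinctive ones, set B intermediate.  Exact zero distances are
#' nudged by machine epsilon (with a message) since ABC analysis requires
#' positive values.
#'
#' @param dist A paired-distance tibble from [paired_distances()].
#' @return A tibble `odor_set`, `odor`, `distance`, `category` (factor
#'   distinctive/intermediate/nondistinctive); the underlying `abc_result`
#'   is attached as attribute `"abc"`.
#' @export
categorize_odors <- function(dist) {
  stopifnot(all(c("odor", "distance") %in% names(dist)))
  values <- dist$distance
  if (any(values == 0)) {
    inform(sprintf("%d zero distance(s) nudged by machine epsilon",
                   sum(values == 0)))
    values[values == 0] <- .Machine$double.eps
  }
  abc <- abc_partition(values, labels = dist$odor)
  category_of <- c(A = "distinctive", B = "intermediate", C = "nondistinctive")
  out <- dist |>
    mutate(category = factor(
      category_of[as.character(abc$assignment$set[match(seq_len(nrow(dist)),
                                                        abc$assignment$item)])],
      levels = c("distinctive", "intermediate", "nondistinctive")
    ))
  structure(out, abc = abc)
}

#' Odors of one displacement category
#'
#' @param categories Output of [categorize_odors()].
#' @param category One of `"distinctive"`, `"intermediate"`,
#'   `"nondistinctive"`.
#' @return Character vector of odor names.
#' @export
odor_category <- function(categories,
                          category = c("distinctive", "intermediate",
                                       "nondistinctive")) {
  category <- match.arg(category)
  categories$odor[categories$category == category]
}
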