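#' Computed ABC analysis
#'
#' Partitions a set of positive values into three ordered disjoint subsets:
#' "A" (the few most important items), "B" (intermediate) and "C" (the
#' trivial many).  The values are sorted in descending order and the
#' discrete cumulative curve of effort (fraction of items considered)
#' versus yield (fraction of the total sum accumulated) is built; the curve
#' runs from (0, 0) to (1, 1), is non-decreasing and concave.  The A|B
#' boundary is the curve point closest (Euclidean) to the ideal point
#' (0, 1); the B|C boundary is the break-even point, the first point at or
#' after which the piecewise slope of the curve drops below 1 (the item's
#' value falls below the mean).  If the break-even point precedes the A|B
#' boundary, B is empty.
#'
#' @param values Positive numeric vector, length >= 1.
#' @param labels Optional item labels; defaults to `names(values)` or
#'   `"item<i>"`.
#' @return An object of class `abc_result` with components `assignment` (a
#'   tibble of item, label, value, rank and set), `curve` (a tibble of
#'   effort/yield points including the (0,0) origin), and the boundary
#'   indices `ab_limit` and `bc_limit` (counted in sorted items).
#' @examples
#' abc_partition(c(8, 2, 1, 1))
#' @export
abc_partition <- function(values, labels = NULL) {
  if (length(values) == 0) {
    abort("ABC analysis needs at least one value",
          class = "odordisc_domain_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("ABC analysis is defined for positive finite values only",
          class = "odordisc_domain_error")
  }
  labels <- labels %||% names(values) %||% sprintf("item%d", seq_along(values))
  n <- length(values)
  ord <- order(values, decreasing = TRUE)  # stable: ties keep input order
  sorted <- values[ord]
  effort <- seq_len(n) / n
  yield <- cumsum(sorted) / sum(sorted)

  ab_limit <- which.min(effort^2 + (1 - yield)^2)
  # piecewise slope of segment i is value_i / mean(values)
  below <- which(sorted < mean(values))
  break_even <- if (length(below)) below[1] else n + 1L
  bc_limit <- max(ab_limit, break_even - 1L)

  set <- rep("C", n)
  set[seq_len(bc_limit)] <- "B"
  set[seq_len(ab_limit)] <- "A"

  assignment <- tibble(
    item = ord,
    label = labels[ord],
    value = sorted,
    rank = seq_len(n),
    set = factor(set, levels = c("A", "B", "C"))
  )
  structure(
    list(
      assignment = assignment,
      curve = tibble(effort = c(0, effort), yield = c(0, yield)),
      ab_limit = ab_limit,
      bc_limit = bc_limit
    ),
    class = "abc_result"
  )
}

#' Items of one ABC set
#'
#' @param x An `abc_result`.
#' @param set `"A"`, `"B"` or `"C"`.
#' @param what `"label"` or `"item"` (original index).
#' @return Character or integer vector of the set members, in descending
#'   value order.
#' @export
abc_set <- function(x, set = c("A", "B", "C"), what = c("label", "item")) {
  stopifnot(inherits(x, "abc_result"))
  set <- match.arg(set)
  what <- match.arg(what)
  x$assignment[[what]][x$assignment$set == set]
}

#' @export
print.abc_result <- function(x, ...) {
  sizes <- table(x$assignment$set)
  cat(sprintf("<abc_result> n = %d: A = %d, B = %d, C = %d\n",
              nrow(x$assignment), sizes["A"], sizes["B"], sizes["C"]))
  invisible(x)
}

#' @rdname abc_partition
#' @param x,object An `abc_result`.
#' @param ... Unused.
#' @method tidy abc_result
#' @export
tidy.abc_result <- function(x, ...) x$assignment

#' @rdname abc_partition
#' @method glance abc_result
#' @export
glance.abc_result <- function(x, ...) {
  sizes <- table(x$assignment$set)
  tibble(
    n = nrow(x$assignment),
    n_a = as.integer(sizes["A"]),
    n_b = as.integer(sizes["B"]),
    n_c = as.integer(sizes["C"]),
    ab_limit = x$ab_limit,
    bc_limit = x$bc_limit
  )
}

#' @rdname abc_partition
#' @method autoplot abc_result
#' @export
autoplot.abc_result <- function(object, ...) {
  pts <- object$curve[-1, ]
  pts$set <- object$assignment$set
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$effort, y = .data$yield)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = pts, ggplot2::aes(colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$ab_limit / nrow(object$assignment),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$bc_limit / nrow(object$assignment),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "effort (fraction of items)",
                  y = "yield (fraction of total value)",
                  colour = "ABC set") +
    ggplot2::theme_minimal()
}

#' Write / read an ABC partition as JSON
#'
#' @param x An `abc_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
abc_to_json <- function(x, path) {
  stopifnot(inherits(x, "abc_result"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("abc_to_json() needs the jsonlite package")
  }
  jsonlite::write_json(
    list(
      sets = list(
        A = abc_set(x, "A"), B = abc_set(x, "B"), C = abc_set(x, "C")
      ),
      curve = x$curve,
      ab_limit = x$ab_limit,
      bc_limit = x$bc_limit
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
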