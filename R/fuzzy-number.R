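#' Triangular or trapezoidal fuzzy numbers
#'
#' A fuzzy number is the unit of all elicitation arithmetic in this package:
#' linguistic terms from expert questionnaires map to fuzzy numbers, panels
#' are aggregated by fuzzy-weighted sums, and pairwise-comparison matrices
#' hold fuzzy judgments. Only convex piecewise-linear numbers are supported:
#' triangular `(a1, a2, a3)` and trapezoidal `(a1, a2, a3, a4)`, with
#' membership 0 outside `[a1, aJ]`, 1 on the kernel, and linear legs in
#' between. A crisp value `v` is the degenerate triangle `(v, v, v)`.
#'
#' Out-of-order breakpoints are rejected, not silently sorted: an unsorted
#' tuple is an elicitation error, and reordering it would fabricate a
#' different opinion.
#'
#' @param points numeric vector of 3 (triangular) or 4 (trapezoidal)
#'   non-decreasing, finite breakpoints.
#' @return An object of class `fuzzy_number`.
#' @examples
#' fuzzy_number(c(1, 1.5, 2))    # "A little more importance" (comparison scale)
#' fuzzy_number(c(5, 5, 5))      # crisp 5
#' fuzzy_number(c(0, 0.1, 0.3, 0.5))
#' @export
fuzzy_number <- function(points) {
  points <- as.numeric(points)
  if (!length(points) %in% c(3L, 4L)) {
    stop("a fuzzy number needs 3 (triangular) or 4 (trapezoidal) breakpoints, got ",
         length(points), call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("fuzzy-number breakpoints must be finite", call. = FALSE)
  }
  if (is.unsorted(points)) {
    stop("fuzzy-number breakpoints must be non-decreasing: (",
         paste(format(points), collapse = ", "), ")", call. = FALSE)
  }
  structure(points, class = "fuzzy_number")
}

#' @export
print.fuzzy_number <- function(x, ...) {
  kind <- if (length(x) == 3L) "triangular" else "trapezoidal"
  cat("<fuzzy_number ", kind, "> (",
      paste(format(unclass(x), digits = 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.fuzzy_number <- function(x, ...) {
  paste0("(", paste(format(unclass(x), digits = 6, trim = TRUE),
                    collapse = ", "), ")")
}

#' @rdname fuzzy_number
#' @param x object to test.
#' @export
is_fuzzy_number <- function(x) inherits(x, "fuzzy_number")

as_fuzzy <- function(x) {
  if (is_fuzzy_number(x)) x else fuzzy_number(x)
}

#' Membership degree of a fuzzy number
#'
#' Evaluates the piecewise-linear membership function at `x` (vectorised).
#'
#' @param f a [fuzzy_number()].
#' @param x numeric vector of evaluation points.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' membership(fuzzy_number(c(1, 1.5, 2)), 1.25)  # 0.5, midway up the left leg
#' @export
membership <- function(f, x) {
  f <- as_fuzzy(f)
  p <- unclass(f)
  J <- length(p)
  a1 <- p[1L]; a2 <- p[2L]; b2 <- p[J - 1L]; b1 <- p[J]
  mu <- numeric(length(x))
  left <- x > a1 & x < a2
  mu[left] <- (x[left] - a1) / (a2 - a1)
  right <- x > b2 & x < b1
  mu[right] <- (b1 - x[right]) / (b1 - b2)
  mu[x >= a2 & x <= b2] <- 1
  mu
}

# promote a triangular number to the trapezoid with a point kernel
fz_promote <- function(f) {
  f <- as_fuzzy(f)
  if (length(f) == 4L) f else fuzzy_number(unclass(f)[c(1L, 2L, 2L, 3L)])
}

#' Fuzzy arithmetic: scaling, addition, reciprocal
#'
#' Pointwise operations on the breakpoints, which for these convex
#' piecewise-linear numbers coincide with interval arithmetic on every
#' alpha-cut. `fz_scale()` multiplies by a non-negative crisp scalar,
#' `fz_add()` adds two numbers of the same shape (a triangular operand is
#' promoted to a point-kernel trapezoid when mixed with a trapezoidal one),
#' and `fz_reciprocal()` inverts a positive-support number by reversing the
#' reciprocals of its breakpoints.
#'
#' @param f,g [fuzzy_number()] objects.
#' @param c non-negative finite scalar.
#' @return A [fuzzy_number()].
#' @examples
#' fz_scale(fuzzy_number(c(1, 1.5, 2)), 0.4)            # (0.4, 0.6, 0.8)
#' fz_add(fuzzy_number(c(1, 1.5, 2)), fuzzy_number(c(1, 1, 1)))
#' fz_reciprocal(fuzzy_number(c(1, 1.5, 2)))            # (0.5, 0.667, 1)
#' @export
fz_scale <- function(f, c) {
  f <- as_fuzzy(f)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("fuzzy scaling needs a single non-negative finite scalar", call. = FALSE)
  }
  fuzzy_number(unclass(f) * c)
}

#' @rdname fz_scale
#' @export
fz_add <- function(f, g) {
  f <- as_fuzzy(f); g <- as_fuzzy(g)
  if (length(f) != length(g)) {
    f <- fz_promote(f); g <- fz_promote(g)
  }
  fuzzy_number(unclass(f) + unclass(g))
}

#' @rdname fz_scale
#' @export
fz_reciprocal <- function(f) {
  f <- as_fuzzy(f)
  if (unclass(f)[1L] <= 0) {
    stop("fuzzy reciprocal needs strictly positive support", call. = FALSE)
  }
  fuzzy_number(rev(1 / unclass(f)))
}

# affine rescale of the breakpoints from interval `from` onto [0, 1]
fz_rescale <- function(f, from) {
  f <- as_fuzzy(f)
  if (from[2L] <= from[1L]) stop("degenerate universe", call. = FALSE)
  fuzzy_number((unclass(f) - from[1L]) / (from[2L] - from[1L]))
}

#' Similarity between two fuzzy opinions
#'
#' The degree of agreement between two experts' fuzzy opinions: one minus
#' the mean absolute difference of corresponding breakpoints,
#' `S = 1 - (1/J) * sum |a_i - b_i|`. For opinions drawn from a scale inside
#' a unit-width universe the result lies in `[0, 1]`, with `S = 1` iff the
#' opinions are identical. A triangular number compared against a
#' trapezoidal one is promoted to a point-kernel trapezoid so that `J = 4`
#' applies to both.
#'
#' @param f,g [fuzzy_number()] objects.
#' @return scalar similarity.
#' @examples
#' fz_similarity(fuzzy_number(c(0.2, 0.3, 0.4)), fuzzy_number(c(0.3, 0.4, 0.5)))  # 0.9
#' @export
fz_similarity <- function(f, g) {
  f <- as_fuzzy(f); g <- as_fuzzy(g)
  if (length(f) != length(g)) {
    f <- fz_promote(f); g <- fz_promote(g)
  }
  1 - mean(abs(unclass(f) - unclass(g)))
}

#' Chen-Hwang max-min defuzzification
#'
#' Converts a fuzzy number supported on `[0, 1]` into a crisp total score
#' using the max-min reference sets: the right score is
#' `sup_x min(mu_F(x), x)` (intersection with the maximising set `mu = x`),
#' the left score is `sup_x min(mu_F(x), 1 - x)`, and the total score is
#' `(right + 1 - left) / 2`. For the piecewise-linear numbers used here both
#' suprema have closed forms on the outer legs: for a triangular
#' `(a, b, c)`, `right = c / (1 + c - b)` and `left = (1 - a) / (1 + b - a)`
#' (a trapezoid `(a, b, c, d)` uses `d, c` on the right leg). Degenerate
#' vertical legs reduce continuously (e.g. `right = c` when `b = c`).
#'
#' Scores are meaningful only on the unit universe; rescale a wider
#' linguistic scale affinely onto `[0, 1]` first (the weighting pipeline
#' does this internally, and the rescaling constant cancels when scores are
#' normalised into weights).
#'
#' @param f a [fuzzy_number()] with support inside `[0, 1]`.
#' @return An object of class `defuzz_scores`: list with elements `right`,
#'   `left` and `total`, each in `[0, 1]`.
#' @examples
#' defuzzify(fuzzy_number(c(0.25, 0.5, 0.75)))  # symmetric: total 0.5
#' @export
defuzzify <- function(f) {
  f <- as_fuzzy(f)
  p <- unclass(f)
  J <- length(p)
  if (p[1L] < -1e-9 || p[J] > 1 + 1e-9) {
    stop("defuzzification requires support inside [0, 1]; got (",
         paste(format(p), collapse = ", "),
         ") - rescale the linguistic scale first", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  right <- p[J] / (1 + p[J] - p[J - 1L])
  left <- (1 - p[1L]) / (1 + p[2L] - p[1L])
  structure(list(right = right, left = left, total = (right + 1 - left) / 2),
            class = "defuzz_scores")
}

#' @export
print.defuzz_scores <- function(x, ...) {
  cat(sprintf("<defuzz_scores> right %.4f | left %.4f | total %.4f\n",
              x$right, x$left, x$total))
  invisible(x)
}
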