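#' Fuzzy pairwise comparison matrix
#'
#' Holds one expert's (or an aggregated panel's) reciprocal matrix of
#' triangular fuzzy judgments over `n >= 2` criteria. Internally the three
#' breakpoints are kept as numeric matrices `l`, `m`, `u`; cell `(j, i)`
#' must equal the reversed reciprocal of cell `(i, j)` and the diagonal is
#' crisp 1.
#'
#' @param l,m,u numeric `n x n` matrices of lower, modal and upper
#'   breakpoints.
#' @param labels character criterion names.
#' @return An object of class `fuzzy_pairwise_matrix`.
#' @seealso [build_matrix()] to construct one from linguistic judgments.
#' @export
fuzzy_pairwise_matrix <- function(l, m, u, labels) {
  n <- length(labels)
  if (n < 2L) stop("a pairwise matrix needs at least 2 criteria", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate criterion labels", call. = FALSE)
  for (mat in list(l, m, u)) {
    if (!is.matrix(mat) || any(dim(mat) != n)) {
      stop("l, m, u must be ", n, " x ", n, " matrices", call. = FALSE)
    }
  }
  if (any(l > m + 1e-12) || any(m > u + 1e-12)) {
    stop("cells must satisfy l <= m <= u", call. = FALSE)
  }
  if (any(abs(diag(l) - 1) > 1e-9) || any(abs(diag(m) - 1) > 1e-9) ||
      any(abs(diag(u) - 1) > 1e-9)) {
    stop("diagonal cells must be crisp (1, 1, 1)", call. = FALSE)
  }
  if (any(l <= 0)) stop("judgments must have positive support", call. = FALSE)
  # reciprocity: cell(j,i) == rev(1/cell(i,j))
  if (max(abs(l - 1 / t(u)), abs(m - 1 / t(m)), abs(u - 1 / t(l))) > 1e-9) {
    stop("matrix is not reciprocal within tolerance", call. = FALSE)
  }
  dimnames(l) <- dimnames(m) <- dimnames(u) <- list(labels, labels)
  structure(list(l = l, m = m, u = u, labels = labels),
            class = "fuzzy_pairwise_matrix")
}

#' @export
print.fuzzy_pairwise_matrix <- function(x, ...) {
  n <- length(x$labels)
  cat("<fuzzy_pairwise_matrix> ", n, " criteria: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  for (i in seq_len(n)) {
    cat("  ", paste(sprintf("(%.3g, %.3g, %.3g)", x$l[i, ], x$m[i, ], x$u[i, ]),
                    collapse = "  "), "\n")
  }
  invisible(x)
}

#' @rdname fuzzy_pairwise_matrix
#' @param mat a `fuzzy_pairwise_matrix`.
#' @param i,j cell indices (integer or label).
#' @export
fpm_cell <- function(mat, i, j) {
  fuzzy_number(c(mat$l[i, j], mat$m[i, j], mat$u[i, j]))
}

#' Build a fuzzy pairwise matrix from linguistic judgments
#'
#' Each unordered pair of criteria must be judged exactly once with a term
#' of the comparison scale; the mirror cell is auto-filled with the
#' reversed reciprocal and the diagonal with crisp 1. `direction`
#' indicates which criterion of the pair is the more important one:
#' `"a_over_b"` (default) places the term's fuzzy number in cell
#' `(a, b)`, `"b_over_a"` in cell `(b, a)`.
#'
#' @param labels character criterion names.
#' @param judgments data frame with columns `criterion_a`, `criterion_b`,
#'   `term` and optionally `direction`.
#' @param scale comparison scale, default [ahp_scale()].
#' @return A [fuzzy_pairwise_matrix()].
#' @examples
#' build_matrix(c("workload", "procedures"),
#'              data.frame(criterion_a = "workload", criterion_b = "procedures",
#'                         term = "A little more importance"))
#' @export
build_matrix <- function(labels, judgments, scale = ahp_scale()) {
  n <- length(labels)
  if (is.null(judgments$direction)) judgments$direction <- "a_over_b"
  l <- m <- u <- diag(1, n)
  dimnames(l) <- dimnames(m) <- dimnames(u) <- list(labels, labels)
  seen <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(judgments))) {
    a <- as.character(judgments$criterion_a[r])
    b <- as.character(judgments$criterion_b[r])
    if (!a %in% labels || !b %in% labels) {
      stop("judgment row ", r, ": unknown criterion '",
           if (a %in% labels) b else a, "'", call. = FALSE)
    }
    if (a == b) stop("judgment row ", r, ": self-comparison '", a, "'", call. = FALSE)
    if (seen[a, b]) stop("pair (", a, ", ", b, ") judged more than once", call. = FALSE)
    seen[a, b] <- seen[b, a] <- TRUE
    f <- scale_term(scale, as.character(judgments$term[r]))
    dir <- match.arg(as.character(judgments$direction[r]), c("a_over_b", "b_over_a"))
    if (dir == "b_over_a") { tmp <- a; a <- b; b <- tmp }
    p <- unclass(f); q <- unclass(fz_reciprocal(f))
    l[a, b] <- p[1L]; m[a, b] <- p[2L]; u[a, b] <- p[3L]
    l[b, a] <- q[1L]; m[b, a] <- q[2L]; u[b, a] <- q[3L]
  }
  unseen <- which(!seen & !diag(TRUE, n), arr.ind = TRUE)
  unseen <- unseen[unseen[, 1L] < unseen[, 2L], , drop = FALSE]
  if (nrow(unseen)) {
    stop("missing judgment for pair (", labels[unseen[1L, 1L]], ", ",
         labels[unseen[1L, 2L]], ")", call. = FALSE)
  }
  fuzzy_pairwise_matrix(l, m, u, labels)
}

#' Aggregate several experts' pairwise matrices
#'
#' Cell-wise weighted arithmetic mean of the fuzzy judgments, followed by a
#' reciprocity repair: an arithmetic mean of reciprocal cells is not itself
#' reciprocal, so for each upper-triangle cell the mean and the reversed
#' reciprocal of the mirror mean are combined by a pointwise geometric
#' mean, and the mirror cell is set to its exact reversed reciprocal. A
#' single matrix (or identical matrices) passes through unchanged.
#'
#' @param matrices list of [fuzzy_pairwise_matrix()] with identical labels.
#' @param weights expert weights summing to 1; default uniform.
#' @return A [fuzzy_pairwise_matrix()].
#' @export
aggregate_matrices <- function(matrices, weights = NULL) {
  k <- length(matrices)
  if (k < 1L) stop("no matrices to aggregate", call. = FALSE)
  labels <- matrices[[1L]]$labels
  for (mt in matrices) {
    if (!identical(mt$labels, labels)) {
      stop("matrices disagree on criterion labels", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-6) {
    stop("need one weight per matrix, summing to 1", call. = FALSE)
  }
  n <- length(labels)
  L <- M <- U <- matrix(0, n, n)
  for (e in seq_len(k)) {
    L <- L + weights[e] * matrices[[e]]$l
    M <- M + weights[e] * matrices[[e]]$m
    U <- U + weights[e] * matrices[[e]]$u
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- c(L[i, j], M[i, j], U[i, j])
      b <- c(1 / U[j, i], 1 / M[j, i], 1 / L[j, i])
      rep_ <- sqrt(a * b)
      L[i, j] <- rep_[1L]; M[i, j] <- rep_[2L]; U[i, j] <- rep_[3L]
      L[j, i] <- 1 / rep_[3L]; M[j, i] <- 1 / rep_[2L]; U[j, i] <- 1 / rep_[1L]
    }
  }
  diag(L) <- diag(M) <- diag(U) <- 1
  fuzzy_pairwise_matrix(L, M, U, labels)
}

#' Fuzzy synthetic extent values
#'
#' For each criterion `i`, the synthetic extent is the fuzzy row sum
#' multiplied by the inverse of the grand sum of all cells,
#' `S_i = (sum_j M_ij) (*) (sum_all M)^-1`, where the inverse of a
#' triangular number is its reversed reciprocal. Extents are the fuzzy
#' analogue of normalised row sums and feed the possibility-degree ranking.
#'
#' @param mat a [fuzzy_pairwise_matrix()].
#' @return named list of triangular [fuzzy_number()] extents.
#' @export
synthetic_extents <- function(mat) {
  stopifnot(inherits(mat, "fuzzy_pairwise_matrix"))
  rl <- rowSums(mat$l); rm_ <- rowSums(mat$m); ru <- rowSums(mat$u)
  gl <- sum(mat$l); gm <- sum(mat$m); gu <- sum(mat$u)
  out <- lapply(seq_along(mat$labels), function(i) {
    fuzzy_number(c(rl[i] / gu, rm_[i] / gm, ru[i] / gl))
  })
  names(out) <- mat$labels
  out
}

#' Degree of possibility that one triangular number exceeds another
#'
#' `possibility(M1, M2)` returns `V(M1 >= M2)`: 1 when `M1`'s modal value
#' is at least `M2`'s; 0 when the supports are disjoint with `M2` entirely
#' to the right (`l2 >= u1`); otherwise the height of the intersection of
#' `M1`'s falling leg with `M2`'s rising leg,
#' `(l2 - u1) / ((m1 - u1) - (m2 - l2))`.
#'
#' @param M1,M2 triangular [fuzzy_number()] objects.
#' @return scalar in `[0, 1]`.
#' @examples
#' possibility(fuzzy_number(c(0.3, 0.4, 0.57)), fuzzy_number(c(0.4, 0.6, 0.86)))
#' @export
possibility <- function(M1, M2) {
  M1 <- as_fuzzy(M1); M2 <- as_fuzzy(M2)
  if (length(M1) != 3L || length(M2) != 3L) {
    stop("possibility degrees are defined for triangular numbers", call. = FALSE)
  }
  p <- unclass(M1); q <- unclass(M2)
  if (p[2L] >= q[2L]) return(1)
  if (q[1L] >= p[3L]) return(0)
  den <- (p[2L] - p[3L]) - (q[2L] - q[1L])
  if (abs(den) < 1e-15) return(0)  # both legs vertical and modes distinct
  (q[1L] - p[3L]) / den
}

#' Crisp weight vector from fuzzy extents
#'
#' Each criterion's raw score is the minimum possibility of its extent
#' exceeding every other extent, `W'_i = min_{k != i} V(S_i >= S_k)`; the
#' raw scores are then normalised to sum to 1. The extent with the largest
#' modal value always scores `W' = 1`, so the normalisation is well
#' defined for any valid extent set. Note that extents wholly dominated by
#' another receive weight exactly 0 — a known property of the
#' extent-analysis ranking.
#'
#' @param extents list of triangular [fuzzy_number()] extents (length >= 2).
#' @return named numeric weights summing to 1, with raw `W'` scores in
#'   attribute `"raw"`.
#' @export
weight_vector <- function(extents) {
  k <- length(extents)
  if (k < 2L) stop("need at least 2 extents", call. = FALSE)
  raw <- vapply(seq_len(k), function(i) {
    min(vapply(setdiff(seq_len(k), i),
               function(j) possibility(extents[[i]], extents[[j]]), 0))
  }, 0)
  if (sum(raw) <= 0) {
    stop("no criterion dominates at any degree; weights undefined", call. = FALSE)
  }
  w <- raw / sum(raw)
  names(w) <- names(extents)
  attr(w, "raw") <- raw
  w
}

#' Extent-analysis weights for one criterion set
#'
#' End-to-end fuzzy AHP over a panel: aggregate the experts' pairwise
#' matrices (default), or derive one weight vector per expert and average,
#' then rank synthetic extents by possibility degrees and normalise.
#'
#' @param matrices list of [fuzzy_pairwise_matrix()] (one per expert), or a
#'   single matrix.
#' @param expert_weights optional weights summing to 1 (default uniform).
#' @param mode `"aggregate"` (pool judgments first, then one extent
#'   analysis) or `"per_expert"` (one weight vector per expert, then a
#'   weighted mean renormalised to 1).
#' @return named numeric weights summing to 1.
#' @export
ahp_weights <- function(matrices, expert_weights = NULL,
                        mode = c("aggregate", "per_expert")) {
  mode <- match.arg(mode)
  if (inherits(matrices, "fuzzy_pairwise_matrix")) matrices <- list(matrices)
  if (mode == "aggregate") {
    agg <- aggregate_matrices(matrices, expert_weights)
    w <- weight_vector(synthetic_extents(agg))
    attr(w, "raw") <- NULL
    return(w)
  }
  k <- length(matrices)
  if (is.null(expert_weights)) expert_weights <- rep(1 / k, k)
  per <- vapply(matrices,
                function(mt) as.numeric(weight_vector(synthetic_extents(mt))),
                numeric(length(matrices[[1L]]$labels)))
  w <- as.numeric(per %*% expert_weights)
  w <- w / sum(w)
  names(w) <- matrices[[1L]]$labels
  w
}
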