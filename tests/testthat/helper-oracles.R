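# Independent dense-grid oracles for the closed-form fuzzy operations.
# They evaluate the defining sup expressions by brute force, sharing no
# derivation with the implementations they check. The objective in every
# case is a pointwise min of quasi-concave piecewise-linear functions,
# hence unimodal, so the sup is located on a dense grid and then refined
# locally to push the discretisation error well below the comparison
# tolerance even for very narrow (steep-legged) numbers.
grid_sup <- function(fun, lo, hi, n = 10001, levels = 3) {
  v_max <- -Inf
  for (l in seq_len(levels)) {
    x <- seq(lo, hi, length.out = n)
    v <- fun(x)
    i <- which.max(v)
    v_max <- max(v_max, v[i])
    lo_new <- x[max(i - 2L, 1L)]
    hi_new <- x[min(i + 2L, length(x))]
    lo <- lo_new; hi <- hi_new
  }
  v_max
}

# Chen-Hwang scores by brute force: sup over x in [0,1] of
# min(mu_F(x), x) and min(mu_F(x), 1 - x).
grid_defuzz <- function(f, ...) {
  right <- grid_sup(function(x) pmin(membership(f, x), x), 0, 1)
  left <- grid_sup(function(x) pmin(membership(f, x), 1 - x), 0, 1)
  list(right = right, left = left, total = (right + 1 - left) / 2)
}

# Degree of possibility V(M1 >= M2) by brute force over the constrained
# sup: sup_{x >= y} min(mu1(x), mu2(y)). For x fixed the best y <= x is
# the running max of mu2, which is non-decreasing, so the objective
# stays unimodal in x and can be refined the same way.
grid_possibility <- function(m1, m2, ...) {
  lo <- min(unclass(m1)[1], unclass(m2)[1])
  hi <- max(unclass(m1)[3], unclass(m2)[3])
  q <- unclass(m2)
  mu2_best <- function(x) ifelse(x >= q[2], 1, membership(m2, x))
  grid_sup(function(x) pmin(membership(m1, x), mu2_best(x)), lo, hi)
}

# random fuzzy numbers with support inside [0, 1]
rand_tri_unit <- function() fuzzy_number(sort(runif(3)))
rand_trap_unit <- function() fuzzy_number(sort(runif(4)))

# random valid pairwise matrix built from random scale judgments
rand_judgment_matrix <- function(n, scale = ahp_scale()) {
  labels <- paste0("c", seq_len(n))
  pairs <- utils::combn(n, 2)
  judgments <- data.frame(
    criterion_a = labels[pairs[1, ]],
    criterion_b = labels[pairs[2, ]],
    term = sample(names(scale), ncol(pairs), replace = TRUE),
    direction = sample(c("a_over_b", "b_over_a"), ncol(pairs), replace = TRUE))
  build_matrix(labels, judgments, scale)
}
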