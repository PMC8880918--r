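test_that("build_matrix fills reciprocals and validates pairs", {
  m <- build_matrix(c("a", "b"),
                    data.frame(criterion_a = "a", criterion_b = "b",
                               term = "Equal importance"))
  expect_equal(unclass(fpm_cell(m, 1, 2)), c(1, 1, 1))
  expect_equal(unclass(fpm_cell(m, 2, 1)), c(1, 1, 1))
  m2 <- build_matrix(c("a", "b"),
                     data.frame(criterion_a = "a", criterion_b = "b",
                                term = "A little more importance"))
  expect_equal(unclass(fpm_cell(m2, 2, 1)), c(0.5, 1 / 1.5, 1))
  expect_error(
    build_matrix(c("a", "b", "c"),
                 data.frame(criterion_a = c("a", "a"),
                            criterion_b = c("b", "c"),
                            term = "Equal importance")),
    "missing judgment .*b, c")
  expect_error(
    build_matrix(c("a", "b"),
                 data.frame(criterion_a = c("a", "b"), criterion_b = c("b", "a"),
                            term = "Equal importance")),
    "more than once")
  expect_error(
    build_matrix(c("a", "b"),
                 data.frame(criterion_a = "a", criterion_b = "b",
                            term = "Slightly nicer")),
    "unknown linguistic term")
  # direction flips which cell receives the term
  m3 <- build_matrix(c("a", "b"),
                     data.frame(criterion_a = "a", criterion_b = "b",
                                term = "Much more importance",
                                direction = "b_over_a"))
  expect_equal(unclass(fpm_cell(m3, 2, 1)), c(2, 2.5, 3))
})

test_that("matrix aggregation is identity-preserving and reciprocal", {
  m1 <- build_matrix(c("a", "b"),
                     data.frame(criterion_a = "a", criterion_b = "b",
                                term = "A little more importance"))
  expect_equal(aggregate_matrices(list(m1))$m, m1$m)
  expect_equal(aggregate_matrices(list(m1, m1), c(0.3, 0.7))$u, m1$u)
  m2 <- build_matrix(c("a", "b"),
                     data.frame(criterion_a = "a", criterion_b = "b",
                                term = "Relatively more importance"))
  agg <- aggregate_matrices(list(m1, m2), c(0.5, 0.5))
  # plain cell-wise mean of cell (1,2) is (1.25, 1.75, 2.25); the repair
  # blends it with the reciprocal of the mirror mean, staying in between
  plain <- c(1.25, 1.75, 2.25)
  mirror <- rev(1 / ((unclass(fz_reciprocal(fpm_cell(m1, 1, 2))) +
                      unclass(fz_reciprocal(fpm_cell(m2, 1, 2)))) / 2))
  got <- unclass(fpm_cell(agg, 1, 2))
  expect_true(all(got >= pmin(plain, mirror) - 1e-12))
  expect_true(all(got <= pmax(plain, mirror) + 1e-12))
  # exact reciprocity after repair
  expect_equal(agg$l, 1 / t(agg$u))
  expect_equal(agg$m, 1 / t(agg$m))
  set.seed(11)
  for (i in 1:10) {
    mats <- replicate(3, rand_judgment_matrix(4), simplify = FALSE)
    a <- aggregate_matrices(mats)
    expect_equal(a$l, 1 / t(a$u))
  }
  expect_error(aggregate_matrices(list(m1, rand_judgment_matrix(3))),
               "labels")
})

test_that("synthetic extents match the hand-computed fuzzy row shares", {
  eq <- build_matrix(c("a", "b"),
                     data.frame(criterion_a = "a", criterion_b = "b",
                                term = "Equal importance"))
  S <- synthetic_extents(eq)
  expect_equal(unclass(S$a), c(2 / 4, 2 / 4, 2 / 4))
  expect_equal(unclass(S$a), unclass(S$b))
  m <- build_matrix(c("a", "b"),
                    data.frame(criterion_a = "a", criterion_b = "b",
                               term = "A little more importance"))
  S2 <- synthetic_extents(m)
  expect_equal(unclass(S2$a), c(2 / 5, 2.5 / (25 / 6), 3 / 3.5))
  expect_equal(unclass(S2$b), c(1.5 / 5, (5 / 3) / (25 / 6), 2 / 3.5))
  # label permutation permutes extents
  set.seed(12)
  mat <- rand_judgment_matrix(4)
  perm <- c(3, 1, 4, 2)
  pm <- fuzzy_pairwise_matrix(mat$l[perm, perm], mat$m[perm, perm],
                              mat$u[perm, perm], mat$labels[perm])
  expect_equal(lapply(synthetic_extents(pm), unclass),
               lapply(synthetic_extents(mat)[perm], unclass))
})

test_that("possibility degrees match geometry", {
  M <- fuzzy_number(c(1, 1.5, 2))
  expect_equal(possibility(M, M), 1)
  expect_equal(possibility(M, fuzzy_number(c(3, 3.5, 4))), 0)  # disjoint
  expect_equal(possibility(fuzzy_number(c(0.3, 0.4, 0.5714)),
                           fuzzy_number(c(0.4, 0.6, 0.8571))),
               0.4615, tolerance = 1e-4)
  # crisp numbers: step overlap
  expect_equal(possibility(fuzzy_number(c(1, 1, 1)), fuzzy_number(c(2, 2, 2))), 0)
  expect_equal(possibility(fuzzy_number(c(2, 2, 2)), fuzzy_number(c(1, 1, 1))), 1)
})

test_that("possibility equals the grid sup/min oracle on random pairs", {
  set.seed(13)
  for (i in 1:100) {
    m1 <- rand_tri_unit(); m2 <- rand_tri_unit()
    expect_lt(abs(possibility(m1, m2) - grid_possibility(m1, m2)), 1e-4)
  }
})

test_that("weight vector ranks extents and normalises", {
  eqs <- list(a = fuzzy_number(c(0.4, 0.5, 0.6)),
              b = fuzzy_number(c(0.4, 0.5, 0.6)))
  expect_equal(unname(weight_vector(eqs)), c(0.5, 0.5), ignore_attr = TRUE)
  ext <- list(a = fuzzy_number(c(0.4, 0.6, 0.8571)),
              b = fuzzy_number(c(0.3, 0.4, 0.5714)))
  w <- weight_vector(ext)
  expect_equal(unname(attr(w, "raw")), c(1, 0.4615), tolerance = 1e-3)
  expect_equal(unname(w), c(0.684, 0.316), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(weight_vector(ext["a"]), "at least 2")
})

test_that("one raw possibility score is always 1; weights sum to 1", {
  set.seed(14)
  for (i in 1:30) {
    mat <- rand_judgment_matrix(sample(3:6, 1))
    w <- weight_vector(synthetic_extents(mat))
    expect_equal(max(attr(w, "raw")), 1)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("ahp_weights: uniformity, dominance, permutation equivariance", {
  all_eq <- build_matrix(c("a", "b", "c"),
                         data.frame(criterion_a = c("a", "a", "b"),
                                    criterion_b = c("b", "c", "c"),
                                    term = "Equal importance"))
  expect_equal(unname(ahp_weights(all_eq)), rep(1 / 3, 3))
  dom <- build_matrix(c("a", "b", "c"),
                      data.frame(criterion_a = c("a", "a", "b"),
                                 criterion_b = c("b", "c", "c"),
                                 term = c("Very much more importance",
                                          "Very much more importance",
                                          "Equal importance")))
  wd <- ahp_weights(dom)
  expect_equal(which.max(wd), c(a = 1))
  set.seed(15)
  mat <- rand_judgment_matrix(5)
  w <- ahp_weights(mat)
  perm <- c(2, 5, 1, 4, 3)
  pm <- fuzzy_pairwise_matrix(mat$l[perm, perm], mat$m[perm, perm],
                              mat$u[perm, perm], mat$labels[perm])
  expect_equal(unname(ahp_weights(pm)), unname(w[perm]), tolerance = 1e-12)
  # per-expert mode agrees with aggregate mode for a lone expert
  expect_equal(ahp_weights(list(mat), mode = "per_expert"), w,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bundled factor weights satisfy their normalisation invariants", {
  tax <- load_taxonomy("default")
  for (cat_ in c("personal", "job", "organization")) {
    w <- taxonomy_weights(tax, cat_)
    expect_equal(sum(w), 1, tolerance = 1e-3 + 1e-9)
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_equal(taxonomy_weights(tax, "job")[["Workload"]], 0.385)
})
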