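panel3 <- expert_weights(expert_profiles(
  c("e1", "e2", "e3"), c(15, 8, 3), c("phd", "master", "bachelor"),
  c("high", "medium", "low")))

test_that("expert weighting normalises ordinal scores", {
  # identical profiles split the weight evenly
  twin <- expert_weights(expert_profiles(c("a", "b"), c(10, 10),
                                         c("master", "master"),
                                         c("high", "high")))
  expect_equal(twin$weight, c(0.5, 0.5))
  # uniform preset overrides profiles entirely
  u <- expert_weights(panel3[1:3, ], "uniform")
  expect_equal(u$weight, rep(1 / 3, 3))
  # custom single-attribute scheme: scores 3 and 1 normalise to 0.75 / 0.25
  scheme <- structure(list(uniform = FALSE, experience_breaks = NULL,
                           levels = list(education = c(phd = 3, diploma = 1))),
                      class = "weight_scheme")
  p <- expert_weights(expert_profiles(c("a", "b"), c(1, 1),
                                      c("phd", "diploma"), c("low", "low")),
                      scheme)
  expect_equal(p$weight, c(0.75, 0.25))
  expect_error(
    expert_weights(expert_profiles("a", 1, "postdoc", "low")),
    "unknown education level")
  expect_equal(sum(panel3$weight), 1)
})

test_that("average agreement follows the pairwise similarity matrix", {
  S <- diag(1, 3)
  S[1, 2] <- S[2, 1] <- 0.9
  S[1, 3] <- S[3, 1] <- 0.9
  S[2, 3] <- S[3, 2] <- 0.8
  expect_equal(average_agreement(S), c(0.9, 0.85, 0.85))
  expect_equal(average_agreement(diag(1, 4)), rep(0, 4))  # off-diagonal zeros
  unanimous <- matrix(1, 3, 3)
  expect_equal(average_agreement(unanimous), rep(1, 3))
  expect_error(average_agreement(matrix(1, 1, 1)), "panel too small")
})

test_that("relative agreement normalises to 1 and rejects total disagreement", {
  expect_equal(relative_agreement(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(relative_agreement(c(0.9, 0.85, 0.85)),
               c(0.9, 0.85, 0.85) / 2.6)
  expect_error(relative_agreement(c(0, 0)), "complete disagreement")
})

test_that("consensus coefficients blend weight and agreement by beta", {
  RA <- c(0.5, 0.5); W <- c(0.6, 0.4)
  expect_equal(consensus_coefficients(RA, W, 0), RA)
  expect_equal(consensus_coefficients(RA, W, 1), W)
  expect_equal(consensus_coefficients(RA, W, 0.4), c(0.54, 0.46))
  expect_error(consensus_coefficients(RA, W, 1.2), "\\[0, 1\\]")
  # sums to 1 for any beta when inputs sum to 1
  set.seed(7)
  for (i in 1:25) {
    m <- sample(2:8, 1)
    RA <- diff(c(0, sort(runif(m - 1)), 1))
    W <- diff(c(0, sort(runif(m - 1)), 1))
    expect_equal(sum(consensus_coefficients(RA, W, runif(1))), 1,
                 tolerance = 1e-9)
  }
})

test_that("aggregation is a convex fuzzy combination", {
  f <- fuzzy_number(c(0.2, 0.3, 0.4)); g <- fuzzy_number(c(0.4, 0.5, 0.6))
  expect_equal(unclass(aggregate_opinions(list(f, g), c(0.5, 0.5))),
               c(0.3, 0.4, 0.5))
  expect_equal(unclass(aggregate_opinions(list(fuzzy_number(c(0, 0.1, 0.2)),
                                               fuzzy_number(c(0.5, 0.6, 0.7))),
                                          c(0.54, 0.46))),
               c(0.23, 0.33, 0.43))
  # identical opinions: aggregate is the common opinion, any coefficients
  expect_equal(unclass(aggregate_opinions(list(f, f, f), c(0.2, 0.5, 0.3))),
               unclass(f))
  expect_error(aggregate_opinions(list(f, g), c(1)), "size mismatch")
  # envelope: aggregate breakpoints inside pointwise min/max of the panel
  set.seed(8)
  for (i in 1:25) {
    ops <- replicate(4, rand_tri_unit(), simplify = FALSE)
    cc <- diff(c(0, sort(runif(3)), 1))
    agg <- unclass(aggregate_opinions(ops, cc))
    env <- sapply(ops, unclass)
    expect_true(all(agg >= apply(env, 1, min) - 1e-12))
    expect_true(all(agg <= apply(env, 1, max) + 1e-12))
  }
})

test_that("psf_weights: symmetry, dominance and normalisation", {
  sets <- list(
    personal = list(e1 = "High", e2 = "High", e3 = "High"),
    job = list(e1 = "High", e2 = "High", e3 = "High"),
    organization = list(e1 = "High", e2 = "High", e3 = "High"))
  res <- psf_weights(panel3, sets)
  expect_equal(unname(res$weights), rep(1 / 3, 3))
  # unanimous panel aggregates to the common opinion exactly
  expect_equal(unclass(res$traces$personal$aggregate),
               unclass(fmagdm_scale()[["High"]]))
  # item rated at scale maximum by everyone dominates minimum-rated items
  sets2 <- list(a = list(e1 = "Very high", e2 = "Very high", e3 = "Very high"),
                b = list(e1 = "Very low", e2 = "Very low", e3 = "Very low"),
                c = list(e1 = "Very low", e2 = "Very low", e3 = "Very low"))
  res2 <- psf_weights(panel3, sets2)
  expect_gt(res2$weights[["a"]], res2$weights[["b"]])
  expect_equal(res2$weights[["b"]], res2$weights[["c"]])
  expect_equal(sum(res2$weights), 1, tolerance = 1e-9)
  expect_true(all(res2$weights >= 0))
})

test_that("permuting the panel permutes traces but not weights", {
  sets <- list(x = list(e1 = "Medium", e2 = "High", e3 = "Fairly low"),
               y = list(e1 = "Low", e2 = "Medium", e3 = "Fairly high"))
  res <- psf_weights(panel3, sets)
  perm <- panel3[c(3, 1, 2), ]
  sets_p <- lapply(sets, function(s) s[c("e3", "e1", "e2")])
  res_p <- psf_weights(perm, lapply(names(sets_p), function(nm) {
    opinion_set(nm, sets_p[[nm]])
  }))
  expect_equal(unname(res_p$weights), unname(res$weights))
  expect_equal(res_p$traces[[1]]$consensus[c(2, 3, 1)],
               res$traces[[1]]$consensus)
})

test_that("consensus trace invariants hold on synthetic panels", {
  spec <- synthetic_spec(seed = 99, n_experts = 6, n_criteria = 3,
                         opinion_noise = 0.3)
  panel <- gen_panel(spec)
  sets <- gen_opinions(spec, panel = panel)
  res <- psf_weights(panel, sets)
  for (tr in res$traces) {
    expect_equal(tr$agreement, t(tr$agreement))
    expect_equal(unname(diag(tr$agreement)), rep(1, 6))
    expect_equal(sum(tr$relative_agreement), 1, tolerance = 1e-9)
    expect_equal(sum(tr$consensus), 1, tolerance = 1e-9)
  }
})

test_that("opinion sets must cover the panel exactly", {
  sets <- list(x = list(e1 = "Medium", e2 = "High"))
  expect_error(psf_weights(panel3, sets), "cover the panel")
  sets2 <- list(x = list(e1 = "Medium", e2 = "High", e3 = "Low", e9 = "Low"))
  expect_error(psf_weights(panel3, sets2), "unknown")
})
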