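#' Synthetic study specification
#'
#' Describes a simulated elicitation with known ground truth, so every
#' pipeline stage can be exercised without real panel data. All
#' randomness in the `gen_*()` generators flows from the single `seed`
#' through fixed per-generator substreams, so a spec reproduces
#' bit-identically.
#'
#' @param seed integer master seed.
#' @param n_experts panel size (default 10, the size of the study panel
#'   this package emulates).
#' @param n_criteria number of criteria for matrix generation.
#' @param true_weights ground-truth importance weights (non-negative, sum
#'   to 1); default generated by [gen_true_weights()].
#' @param opinion_noise probability that a generated judgment drifts one
#'   scale step off the snapped term (default 0.1).
#' @param rating_profile per-category `c(mean, sd)` pairs on the 1-9
#'   rating scale; the default matches the magnitude of the bundled
#'   case-study ratings.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_experts = 10, n_criteria = NULL,
                           true_weights = NULL, opinion_noise = 0.1,
                           rating_profile = list(
                             personal = c(mean = 6.2, sd = 0.25),
                             job = c(mean = 4.2, sd = 0.45),
                             organization = c(mean = 4.1, sd = 0.55))) {
  seed <- as.integer(seed)
  if (!is.finite(seed)) stop("seed must be an integer", call. = FALSE)
  if (n_experts < 2) stop("n_experts must be at least 2", call. = FALSE)
  if (is.null(true_weights)) {
    if (is.null(n_criteria)) n_criteria <- 3L
    true_weights <- gen_true_weights(n_criteria, seed)
  }
  if (any(true_weights < 0) || abs(sum(true_weights) - 1) > 1e-9) {
    stop("true_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(n_criteria)) n_criteria <- length(true_weights)
  if (n_criteria != length(true_weights)) {
    stop("n_criteria does not match length(true_weights)", call. = FALSE)
  }
  if (opinion_noise < 0 || opinion_noise > 1) {
    stop("opinion_noise is a probability", call. = FALSE)
  }
  structure(list(seed = seed, n_experts = as.integer(n_experts),
                 n_criteria = as.integer(n_criteria),
                 true_weights = true_weights,
                 opinion_noise = opinion_noise,
                 rating_profile = rating_profile),
            class = "synthetic_spec")
}

# fixed substreams per generator, derived from the master seed
derive_seed <- function(seed, stream) {
  as.integer((1103515245 * (as.numeric(seed) %% 65536) + 12345 + stream) %%
               2147483647)
}

#' Ground-truth weight vectors distinguishable on the comparison scale
#'
#' Draws a weight vector whose consecutive sorted ratios are uniform in
#' `[1.3, 1.8]` — wide enough apart that the five-term comparison scale
#' (ratio steps 1, 1.5, 2, 2.5, 3) can resolve neighbouring criteria, as
#' real panels are only asked to compare criteria they can tell apart —
#' then shuffles the order.
#'
#' @param n number of criteria.
#' @param seed integer seed.
#' @return numeric weights, non-negative, summing to 1.
#' @export
gen_true_weights <- function(n, seed) {
  if (n < 2) stop("need at least 2 criteria", call. = FALSE)
  set.seed(derive_seed(seed, 7L))
  ratios <- stats::runif(n - 1, 1.3, 1.8)
  w <- rev(cumprod(c(1, ratios)))
  w <- sample(w)
  w / sum(w)
}

#' Generate a synthetic expert panel
#'
#' Profiles with ordinal attributes sampled uniformly over the default
#' weighting scheme's levels and experience uniform over 1-30 years;
#' weights come from [expert_weights()] with the default scheme.
#'
#' @param spec a [synthetic_spec()].
#' @return An [expert_profiles()] frame with a `weight` column.
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  m <- spec$n_experts
  profiles <- expert_profiles(
    id = sprintf("E%02d", seq_len(m)),
    experience = sample(1:30, m, replace = TRUE),
    education = sample(c("diploma", "bachelor", "master", "phd"), m, replace = TRUE),
    relevancy = sample(c("low", "medium", "high"), m, replace = TRUE))
  expert_weights(profiles, "default")
}

snap_to_scale <- function(target, scale) {
  modes <- vapply(scale, function(f) {
    p <- unclass(f)
    p[ceiling(length(p) / 2)]
  }, 0)
  which.min(abs(modes - target))
}

#' Generate linguistic importance opinions with known ground truth
#'
#' For each item, every expert's term is the scale term whose modal value
#' is nearest the item's true importance (scaled so the most important
#' item sits at the top of the scale), perturbed by one scale step with
#' probability `opinion_noise`.
#'
#' @param spec a [synthetic_spec()].
#' @param items item labels, default `item1..itemK`.
#' @param panel panel frame from [gen_panel()] (regenerated when absent).
#' @param scale elicitation scale, default [fmagdm_scale()].
#' @return named list of [opinion_set()] objects.
#' @export
gen_opinions <- function(spec, items = NULL, panel = NULL,
                         scale = fmagdm_scale()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(panel)) panel <- gen_panel(spec)
  if (is.null(items)) {
    items <- names(spec$true_weights)
    if (is.null(items)) items <- paste0("item", seq_along(spec$true_weights))
  }
  stopifnot(length(items) == length(spec$true_weights))
  set.seed(derive_seed(spec$seed, 2L))
  targets <- spec$true_weights / max(spec$true_weights)
  n_terms <- length(scale)
  sets <- lapply(seq_along(items), function(i) {
    base <- snap_to_scale(targets[i], scale)
    idx <- vapply(seq_len(nrow(panel)), function(e) {
      j <- base
      if (stats::runif(1) < spec$opinion_noise) {
        j <- j + sample(c(-1L, 1L), 1L)
      }
      min(max(j, 1L), n_terms)
    }, 0L)
    opinion_set(items[i], setNames(as.list(names(scale)[idx]), panel$id))
  })
  names(sets) <- items
  sets
}

# signed ladder over the comparison scale: -k is the reciprocal of term k,
# 1 is "equal"; index 0 does not exist
scale_ladder <- function(scale) {
  k <- length(scale)
  c(-(k:2), 1:k)
}

ladder_fuzzy <- function(scale, s) {
  f <- scale[[abs(s)]]
  if (s < 0) fz_reciprocal(f) else f
}

ladder_ratio <- function(scale, s) {
  p <- unclass(scale[[abs(s)]])
  if (s < 0) 1 / p[2L] else p[2L]
}

#' Generate fuzzy pairwise matrices from a ground-truth weight vector
#'
#' For every expert and every pair of criteria, the true ratio
#' `w_i / w_j` is snapped (on the log scale) to the nearest comparison
#' term or reciprocal term, then perturbed one ladder step with
#' probability `opinion_noise`. Generated matrices are reciprocal by
#' construction.
#'
#' @param spec a [synthetic_spec()].
#' @param labels criterion labels, default `c1..cK`.
#' @param scale comparison scale, default [ahp_scale()].
#' @return list of [fuzzy_pairwise_matrix()], one per expert.
#' @export
gen_matrices <- function(spec, labels = NULL, scale = ahp_scale()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_criteria
  if (n < 2) stop("need at least 2 criteria", call. = FALSE)
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  set.seed(derive_seed(spec$seed, 3L))
  ladder <- scale_ladder(scale)
  log_ratios <- vapply(ladder, function(s) log(ladder_ratio(scale, s)), 0)
  w <- spec$true_weights
  lapply(seq_len(spec$n_experts), function(e) {
    l <- m <- u <- diag(1, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        pos <- which.min(abs(log_ratios - log(w[i] / w[j])))
        if (stats::runif(1) < spec$opinion_noise) {
          pos <- min(max(pos + sample(c(-1L, 1L), 1L), 1L), length(ladder))
        }
        f <- unclass(ladder_fuzzy(scale, ladder[pos]))
        g <- rev(1 / f)
        l[i, j] <- f[1L]; m[i, j] <- f[2L]; u[i, j] <- f[3L]
        l[j, i] <- g[1L]; m[j, i] <- g[2L]; u[j, i] <- g[3L]
      }
    }
    fuzzy_pairwise_matrix(l, m, u, labels)
  })
}

#' Generate a category-level rating sheet
#'
#' Ratings are drawn per subtask and category from the spec's normal
#' rating profile and clipped to the 1-9 scale.
#'
#' @param spec a [synthetic_spec()].
#' @param tasks a [task_analysis()].
#' @return A [rating_sheet()].
#' @export
gen_ratings <- function(spec, tasks) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 4L))
  cats <- names(spec$rating_profile)
  ids <- tasks$subtask_id
  rows <- expand.grid(name = cats, subtask_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rating <- vapply(seq_len(nrow(rows)), function(r) {
    prof <- spec$rating_profile[[rows$name[r]]]
    min(max(stats::rnorm(1, prof[["mean"]], prof[["sd"]]), 1), 9)
  }, 0)
  rating_sheet(rows$subtask_id, "category", rows$name, rating)
}
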