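#' Expert panel profiles
#'
#' Builds a validated panel table. Each expert carries the three attributes
#' used for importance weighting — years of work experience, education
#' level, and relevancy of their specialty to the assessed process — plus,
#' after [expert_weights()], a normalised weight `W(E_u)`.
#'
#' @param id character labels, unique.
#' @param experience numeric years of work experience.
#' @param education character, one of the levels of the weighting scheme
#'   (default scheme: `diploma`, `bachelor`, `master`, `phd`).
#' @param relevancy character, relevancy of specialty (default scheme:
#'   `low`, `medium`, `high`).
#' @return A data frame of class `expert_profiles`.
#' @export
expert_profiles <- function(id, experience, education, relevancy) {
  if (anyDuplicated(id)) stop("duplicate expert ids", call. = FALSE)
  if (length(id) < 1L) stop("empty panel", call. = FALSE)
  if (!is.numeric(experience) || any(!is.finite(experience)) || any(experience < 0)) {
    stop("experience must be non-negative years", call. = FALSE)
  }
  out <- data.frame(id = as.character(id), experience = experience,
                    education = as.character(education),
                    relevancy = as.character(relevancy),
                    stringsAsFactors = FALSE)
  class(out) <- c("expert_profiles", "data.frame")
  out
}

#' Expert weighting schemes
#'
#' The similarity aggregation method blends each expert's relative
#' agreement with an importance weight `W(E_u)` derived from their profile.
#' No canonical scoring formula exists for the profile attributes, so the
#' package uses a transparent additive ordinal score: experience in years is
#' binned (`< 5`, `5-10`, `10-20`, `>= 20` years scoring 1-4), education and
#' relevancy levels score their ordinal position, the three parts are
#' summed, and scores are normalised across the panel so that weights sum
#' to 1. `expert_weight_scheme("uniform")` forces `W(E_u) = 1/m` for all
#' experts (the panel-of-equals case, equivalent to `beta = 0` downstream).
#'
#' A custom scheme is a list with elements `experience_breaks` (ascending
#' cut points; `NULL` to ignore experience) and `levels` (named list of
#' named numeric score vectors, matched against profile columns).
#'
#' @param name `"default"` or `"uniform"`.
#' @return A list describing the scheme.
#' @export
expert_weight_scheme <- function(name = "default") {
  name <- match.arg(name, c("default", "uniform"))
  if (name == "uniform") return(structure(list(uniform = TRUE), class = "weight_scheme"))
  structure(list(
    uniform = FALSE,
    experience_breaks = c(5, 10, 20),
    levels = list(
      education = c(diploma = 1, bachelor = 2, master = 3, phd = 4),
      relevancy = c(low = 1, medium = 2, high = 3)
    )
  ), class = "weight_scheme")
}

score_expert <- function(profiles, scheme) {
  score <- numeric(nrow(profiles))
  if (!is.null(scheme$experience_breaks)) {
    score <- score + findInterval(profiles$experience, scheme$experience_breaks) + 1
  }
  for (attr_name in names(scheme$levels)) {
    lv <- scheme$levels[[attr_name]]
    val <- profiles[[attr_name]]
    if (is.null(val)) stop("profiles lack attribute '", attr_name, "'", call. = FALSE)
    bad <- !val %in% names(lv)
    if (any(bad)) {
      stop("unknown ", attr_name, " level '", val[which(bad)[1L]],
           "'; scheme defines: ", paste(names(lv), collapse = ", "), call. = FALSE)
    }
    score <- score + lv[val]
  }
  unname(score)
}

#' Compute panel weights from profiles
#'
#' @param profiles an [expert_profiles()] data frame.
#' @param scheme a scheme from [expert_weight_scheme()], or one of the
#'   preset names `"default"` / `"uniform"`.
#' @return `profiles` with a `weight` column summing to 1.
#' @examples
#' p <- expert_profiles(c("e1", "e2"), c(12, 3), c("phd", "bachelor"),
#'                      c("high", "low"))
#' expert_weights(p)
#' @export
expert_weights <- function(profiles, scheme = "default") {
  stopifnot(inherits(profiles, "expert_profiles") || is.data.frame(profiles))
  if (is.character(scheme)) scheme <- expert_weight_scheme(scheme)
  m <- nrow(profiles)
  if (isTRUE(scheme$uniform)) {
    profiles$weight <- rep(1 / m, m)
    return(profiles)
  }
  score <- score_expert(profiles, scheme)
  if (sum(score) <= 0) stop("all expert scores are zero", call. = FALSE)
  profiles$weight <- score / sum(score)
  profiles
}

#' An opinion set: one judged item, one fuzzy opinion per expert
#'
#' @param item label of the judged item (e.g. a PSF category).
#' @param opinions named list (expert id -> fuzzy number, or a term label
#'   resolved later against a scale).
#' @return An object of class `opinion_set`.
#' @export
opinion_set <- function(item, opinions) {
  if (length(opinions) < 2L) stop("an opinion set needs at least 2 experts", call. = FALSE)
  if (is.null(names(opinions)) || any(!nzchar(names(opinions)))) {
    stop("opinions must be named by expert id", call. = FALSE)
  }
  if (anyDuplicated(names(opinions))) {
    stop("duplicate expert in opinion set '", item, "'", call. = FALSE)
  }
  structure(list(item = item, opinions = opinions), class = "opinion_set")
}

#' Pairwise agreement matrix of a panel's opinions
#'
#' @param opinions list of [fuzzy_number()] opinions (one per expert).
#' @return symmetric `m x m` matrix of similarities with unit diagonal.
#' @export
agreement_matrix <- function(opinions) {
  m <- length(opinions)
  if (m < 2L) stop("panel too small: need at least 2 experts", call. = FALSE)
  S <- diag(1, m)
  for (u in seq_len(m - 1L)) {
    for (v in seq.int(u + 1L, m)) {
      S[u, v] <- S[v, u] <- fz_similarity(opinions[[u]], opinions[[v]])
    }
  }
  dimnames(S) <- list(names(opinions), names(opinions))
  S
}

#' Similarity aggregation method: agreement statistics
#'
#' `average_agreement()` gives each expert's mean similarity to the rest of
#' the panel, `AA(E_u) = (1/(m-1)) * sum_{v != u} S_uv`.
#' `relative_agreement()` normalises the vector to sum to 1.
#' `consensus_coefficients()` blends relative agreement with the expert
#' importance weights: `CC(E_u) = beta * W(E_u) + (1 - beta) * RA(E_u)`;
#' with `beta = 0` all experts count only through their agreement (the
#' panel-of-equals limit), with `beta = 1` only through their profile
#' weight.
#'
#' @param agreement symmetric agreement matrix from [agreement_matrix()].
#' @return numeric vector, one entry per expert.
#' @export
average_agreement <- function(agreement) {
  m <- nrow(agreement)
  if (is.null(m) || m < 2L || ncol(agreement) != m) {
    stop("panel too small: average agreement needs an m x m matrix with m >= 2",
         call. = FALSE)
  }
  (rowSums(agreement) - diag(agreement)) / (m - 1)
}

#' @rdname average_agreement
#' @param AA vector of average agreements.
#' @export
relative_agreement <- function(AA) {
  if (sum(AA) <= 0) {
    stop("complete disagreement: average agreements sum to zero, ",
         "relative agreement is undefined", call. = FALSE)
  }
  AA / sum(AA)
}

#' @rdname average_agreement
#' @param RA vector of relative agreements (sums to 1).
#' @param weights expert importance weights `W(E_u)` (sum to 1).
#' @param beta blend factor in `[0, 1]`.
#' @export
consensus_coefficients <- function(RA, weights, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]", call. = FALSE)
  }
  if (length(RA) != length(weights)) {
    stop("RA and weights differ in length", call. = FALSE)
  }
  if (abs(sum(RA) - 1) > 1e-6 || abs(sum(weights) - 1) > 1e-6) {
    stop("RA and expert weights must each sum to 1", call. = FALSE)
  }
  beta * weights + (1 - beta) * RA
}

#' Aggregate a panel's fuzzy opinions
#'
#' The consensus opinion is the fuzzy-weighted sum
#' `R_AG = sum_u CC(E_u) * R(E_u)`; because the coefficients sum to 1 the
#' aggregate stays inside the pointwise envelope of the panel's opinions.
#'
#' @param opinions list of [fuzzy_number()] opinions.
#' @param CC consensus coefficients summing to 1.
#' @return A [fuzzy_number()].
#' @export
aggregate_opinions <- function(opinions, CC) {
  if (length(opinions) != length(CC)) {
    stop("coefficient/opinion size mismatch", call. = FALSE)
  }
  if (abs(sum(CC) - 1) > 1e-6) stop("coefficients must sum to 1", call. = FALSE)
  opinions <- lapply(opinions, as_fuzzy)
  if (length(unique(vapply(opinions, length, 1L))) > 1L) {
    opinions <- lapply(opinions, fz_promote)
  }
  Reduce(fz_add, Map(fz_scale, opinions, CC))
}

#' Full SAM consensus for one item
#'
#' Runs the similarity aggregation chain for one judged item: agreement
#' matrix, average and relative agreement, consensus coefficients, fuzzy
#' aggregation, and Chen-Hwang defuzzification of the aggregate (after an
#' affine rescale of the universe onto `[0, 1]`).
#'
#' @param opinions named list of [fuzzy_number()] opinions, one per expert.
#' @param weights expert importance weights (sum to 1), same order.
#' @param beta blend factor in `[0, 1]`.
#' @param universe numeric length-2, the universe of the elicitation scale
#'   (rescaled onto `[0, 1]` before defuzzification).
#' @return An object of class `consensus_trace`: list with `agreement`,
#'   `average_agreement`, `relative_agreement`, `consensus`, `beta`,
#'   `aggregate` (fuzzy number on the original universe), `scores`
#'   (defuzzification of the rescaled aggregate) and `defuzzified` (its
#'   total score).
#' @export
sam_consensus <- function(opinions, weights, beta = 0.4, universe = c(0, 1)) {
  opinions <- lapply(opinions, as_fuzzy)
  S <- agreement_matrix(opinions)
  AA <- average_agreement(S)
  RA <- relative_agreement(AA)
  CC <- consensus_coefficients(RA, weights, beta)
  agg <- aggregate_opinions(opinions, CC)
  scores <- defuzzify(fz_rescale(agg, universe))
  structure(list(agreement = S, average_agreement = AA,
                 relative_agreement = RA, consensus = CC, beta = beta,
                 aggregate = agg, scores = scores,
                 defuzzified = scores$total),
            class = "consensus_trace")
}

#' @export
print.consensus_trace <- function(x, ...) {
  cat("<consensus_trace> m =", length(x$consensus), "experts, beta =", x$beta, "\n")
  cat("  CC:", paste(sprintf("%.4f", x$consensus), collapse = " "), "\n")
  cat("  aggregate:", format(x$aggregate), " total score:",
      sprintf("%.4f", x$defuzzified), "\n")
  invisible(x)
}

#' PSF category weights from a panel's linguistic judgments
#'
#' End-to-end fuzzy multiple attributive group decision making: for every
#' judged item the panel's linguistic opinions are aggregated by the
#' similarity aggregation method and defuzzified; the crisp total scores
#' are then normalised across items into a weight vector summing to 1.
#'
#' Note that the weights the bundled case study uses
#' ([published_category_weights()]) came from an elicitation whose raw
#' judgments are not distributed with the package; this function is the
#' recompute path for panels you elicit yourself.
#'
#' @param panel an [expert_profiles()] frame, with or without a `weight`
#'   column (weights are computed with `scheme` when absent).
#' @param opinion_sets list of [opinion_set()] objects (or named list of
#'   named term lists), all covering the same panel.
#' @param beta SAM blend factor, default 0.4.
#' @param scale [linguistic_scale()] used to resolve term labels.
#' @param scheme expert weighting scheme (see [expert_weights()]).
#' @return An object of class `psf_weight_result`: list with `weights`
#'   (named, sums to 1) and `traces` (per-item [sam_consensus()] traces).
#' @export
psf_weights <- function(panel, opinion_sets, beta = 0.4,
                        scale = fmagdm_scale(), scheme = "default") {
  if (is.null(panel$weight)) panel <- expert_weights(panel, scheme)
  if (abs(sum(panel$weight) - 1) > 1e-9) {
    stop("panel weights must sum to 1", call. = FALSE)
  }
  sets <- lapply(seq_along(opinion_sets), function(i) {
    s <- opinion_sets[[i]]
    if (inherits(s, "opinion_set")) return(s)
    nm <- names(opinion_sets)[i]
    if (is.null(nm) || !nzchar(nm)) stop("unnamed opinion set", call. = FALSE)
    opinion_set(nm, s)
  })
  items <- vapply(sets, function(s) s$item, "")
  if (anyDuplicated(items)) stop("duplicate item in opinion sets", call. = FALSE)
  universe <- scale_universe(scale)
  traces <- lapply(sets, function(s) {
    ops <- s$opinions
    missing_ids <- setdiff(panel$id, names(ops))
    extra_ids <- setdiff(names(ops), panel$id)
    if (length(missing_ids) || length(extra_ids)) {
      stop("item '", s$item, "': opinions must cover the panel exactly",
           if (length(missing_ids)) paste0(" (missing: ",
                                           paste(missing_ids, collapse = ", "), ")"),
           if (length(extra_ids)) paste0(" (unknown: ",
                                         paste(extra_ids, collapse = ", "), ")"),
           call. = FALSE)
    }
    ops <- lapply(ops[panel$id], function(o) scale_term(scale, o))
    sam_consensus(ops, panel$weight, beta, universe)
  })
  names(traces) <- items
  totals <- vapply(traces, function(t) t$defuzzified, 0)
  if (sum(totals) <= 0) stop("all items defuzzified to zero", call. = FALSE)
  weights <- totals / sum(totals)
  structure(list(weights = weights, traces = traces, beta = beta),
            class = "psf_weight_result")
}

#' @export
print.psf_weight_result <- function(x, ...) {
  cat("<psf_weight_result> beta =", x$beta, "\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-28s %.4f  (total score %.4f)\n", nm, x$weights[[nm]],
                x$traces[[nm]]$defuzzified))
  }
  invisible(x)
}
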