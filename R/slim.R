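#' Log-linear SLIM calibration
#'
#' The Success Likelihood Index Methodology maps the index to a
#' probability through `log10(HEP) = a * SLI + b`. The two constants are
#' fixed by anchoring the worst situation (`SLI = sli_min`, all factors at
#' their worst) to `hep_max` and the best (`SLI = sli_max`) to `hep_min`.
#' With the default anchors `hep_min = 1e-4`, `hep_max = 1` over
#' `SLI in [1, 9]` this gives `a = -0.5`, `b = 0.5`.
#'
#' @param hep_min,hep_max probabilities, `0 < hep_min < hep_max <= 1`.
#' @param sli_min,sli_max index range, `sli_min < sli_max`.
#' @return An object of class `slim_calibration` with elements `a`, `b`
#'   and the four anchors.
#' @examples
#' slim_calibration()  # a = -0.5, b = 0.5
#' @export
slim_calibration <- function(hep_min = 1e-4, hep_max = 1,
                             sli_min = 1, sli_max = 9) {
  if (!is.finite(hep_min) || !is.finite(hep_max) ||
      hep_min <= 0 || hep_max > 1 || hep_min >= hep_max) {
    stop("need 0 < hep_min < hep_max <= 1", call. = FALSE)
  }
  if (!is.finite(sli_min) || !is.finite(sli_max) || sli_min >= sli_max) {
    stop("degenerate SLI range: need sli_min < sli_max", call. = FALSE)
  }
  a <- (log10(hep_min) - log10(hep_max)) / (sli_max - sli_min)
  b <- log10(hep_max) - a * sli_min
  structure(list(a = a, b = b, hep_min = hep_min, hep_max = hep_max,
                 sli_min = sli_min, sli_max = sli_max),
            class = "slim_calibration")
}

#' @export
print.slim_calibration <- function(x, ...) {
  cat(sprintf("<slim_calibration> log10(HEP) = %.4g * SLI + %.4g  (HEP in [%g, %g], SLI in [%g, %g])\n",
              x$a, x$b, x$hep_min, x$hep_max, x$sli_min, x$sli_max))
  invisible(x)
}

#' Category weights of the bundled case study
#'
#' The personal / job / organization weights `(0.367, 0.311, 0.321)` of the
#' emergency-department case study, exactly as published. They are a
#' bundled fixture: the panel's raw linguistic judgments behind them were
#' never released, so they cannot be recomputed with [psf_weights()]. As
#' printed they sum to 0.999 (a rounding artefact); they are used
#' unnormalised because the case-study rating table is only reproducible
#' with the printed values.
#'
#' @return named numeric vector `c(personal, job, organization)`.
#' @export
published_category_weights <- function() {
  c(personal = 0.367, job = 0.311, organization = 0.321)
}

check_category_weights <- function(weights) {
  need <- c("personal", "job", "organization")
  if (is.null(names(weights)) || !all(need %in% names(weights))) {
    stop("category weights must be named personal, job, organization", call. = FALSE)
  }
  weights <- weights[need]
  if (any(weights < 0) || any(weights > 1)) {
    stop("category weights must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(weights)
  if (s < 0.99 || s > 1.01) {
    stop("category weights must sum to ~1 (got ", format(s), ")", call. = FALSE)
  }
  weights
}

#' Weighted category rating from factor ratings
#'
#' A PSF category's rating is the weight-averaged rating of its factors,
#' `R = sum_i r_i * w_i`, with every weighted factor rated on the 1 (worst)
#' to 9 (best) scale.
#'
#' @param ratings named numeric factor ratings in `[1, 9]`.
#' @param weights named numeric factor weights (summing to ~1).
#' @return scalar category rating.
#' @export
category_rating <- function(ratings, weights) {
  missing_r <- setdiff(names(weights), names(ratings))
  if (length(missing_r)) {
    stop("missing rating for weighted factor(s): ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-2) {
    stop("factor weights must sum to ~1 (got ", format(s), ")", call. = FALSE)
  }
  r <- ratings[names(weights)]
  if (any(r < 1 - 1e-9) || any(r > 9 + 1e-9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  sum(r * weights)
}

#' Success Likelihood Index
#'
#' The SLI of a subtask is the category-weighted sum of its three PSF
#' ratings, `SLI = w_per * R_per + w_job * R_job + w_org * R_org`
#' (vectorised over subtasks). With the published case-study weights this
#' is `0.367 R_per + 0.311 R_job + 0.321 R_org`; because those printed
#' weights sum to 0.999 the attainable SLI maximum is 8.991, slightly
#' inside the nominal `[1, 9]` range.
#'
#' @param r_per,r_job,r_org numeric ratings in `[1, 9]`.
#' @param weights named category weights (see
#'   [published_category_weights()]).
#' @return numeric SLI values.
#' @export
sli <- function(r_per, r_job, r_org, weights = published_category_weights()) {
  weights <- check_category_weights(weights)
  r <- cbind(r_per, r_job, r_org)
  if (any(r < 1 - 1e-9) || any(r > 9 + 1e-9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  as.numeric(r %*% weights)
}

#' Human error probability from an SLI value
#'
#' `HEP = 10^(a * SLI + b)` under a [slim_calibration()], clamped to the
#' calibration's probability bounds; an SLI outside the nominal range
#' triggers a warning but not an error (the published weights cap SLI at
#' 8.991 rather than 9, which is expected drift).
#'
#' @param sli numeric SLI values.
#' @param cal a [slim_calibration()].
#' @return numeric probabilities.
#' @examples
#' hep(4.3699)  # ~0.0207
#' @export
hep <- function(sli, cal = slim_calibration()) {
  stopifnot(inherits(cal, "slim_calibration"))
  out_of_range <- sli < cal$sli_min - 1e-9 | sli > cal$sli_max + 1e-9
  if (any(out_of_range)) {
    warning(sum(out_of_range), " SLI value(s) outside the nominal [",
            cal$sli_min, ", ", cal$sli_max, "] range; HEP clamped to [",
            cal$hep_min, ", ", cal$hep_max, "]", call. = FALSE)
  }
  pmin(pmax(10^(cal$a * sli + cal$b), cal$hep_min), cal$hep_max)
}

#' Assess human error probability for every subtask
#'
#' Runs the full SLIM evaluation over a task analysis: resolves each
#' subtask's three category ratings (either given directly at category
#' level, or computed from factor-level ratings through the taxonomy's
#' factor weights), computes the SLI and the HEP, and flags the highest-
#' and lowest-risk subtasks (ties share the flag).
#'
#' @param tasks a [task_analysis()].
#' @param sheet a [rating_sheet()] covering every subtask.
#' @param taxonomy a [psf_taxonomy()], needed when the sheet carries
#'   factor-level ratings.
#' @param weights category weights, default the published case-study
#'   fixture.
#' @param cal a [slim_calibration()].
#' @return A data frame of class `hep_results` with columns `subtask_id`,
#'   `subtask`, `r_personal`, `r_job`, `r_organization`, `sli`, `hep`, and
#'   attributes `max_hep_subtasks` / `min_hep_subtasks`.
#' @export
assess <- function(tasks, sheet, taxonomy = load_taxonomy("default"),
                   weights = published_category_weights(),
                   cal = slim_calibration()) {
  weights <- check_category_weights(weights)
  ids <- tasks$subtask_id
  if (length(ids) == 0L) {
    out <- data.frame(subtask_id = character(), subtask = character(),
                      r_personal = numeric(), r_job = numeric(),
                      r_organization = numeric(), sli = numeric(),
                      hep = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("hep_results", "data.frame")
    attr(out, "max_hep_subtasks") <- character()
    attr(out, "min_hep_subtasks") <- character()
    return(out)
  }
  cats <- c("personal", "job", "organization")
  rmat <- matrix(NA_real_, length(ids), 3L, dimnames = list(ids, cats))
  for (id in ids) {
    rows <- sheet[sheet$subtask_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) stop("subtask ", id, " is unrated", call. = FALSE)
    if (all(rows$level == "category")) {
      found <- setNames(rows$rating, rows$name)
      if (!all(cats %in% names(found))) {
        stop("subtask ", id, ": category-level sheet must rate ",
             "personal, job and organization", call. = FALSE)
      }
      rmat[id, ] <- found[cats]
    } else if (all(rows$level == "subpsf")) {
      for (cat in cats) {
        w <- taxonomy_weights(taxonomy, cat)
        rmat[id, cat] <- category_rating(setNames(rows$rating, rows$name), w)
      }
    } else {
      stop("subtask ", id, ": mixed category/factor rating levels", call. = FALSE)
    }
  }
  sli_v <- sli(rmat[, 1L], rmat[, 2L], rmat[, 3L], weights)
  hep_v <- hep(sli_v, cal)
  out <- data.frame(subtask_id = ids, subtask = tasks$subtask,
                    r_personal = rmat[, 1L], r_job = rmat[, 2L],
                    r_organization = rmat[, 3L], sli = sli_v, hep = hep_v,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("hep_results", "data.frame")
  attr(out, "max_hep_subtasks") <- ids[abs(hep_v - max(hep_v)) < 1e-12]
  attr(out, "min_hep_subtasks") <- ids[abs(hep_v - min(hep_v)) < 1e-12]
  out
}

#' @export
print.hep_results <- function(x, digits = 4, ...) {
  cat("<hep_results> ", nrow(x), " subtasks\n", sep = "")
  if (nrow(x)) {
    df <- data.frame(subtask = x$subtask_id,
                     R_P = round(x$r_personal, 3), R_J = round(x$r_job, 3),
                     R_O = round(x$r_organization, 3),
                     SLI = round(x$sli, digits),
                     HEP = signif(x$hep, digits))
    print(df, row.names = FALSE)
    cat("highest HEP:", paste(attr(x, "max_hep_subtasks"), collapse = ", "),
        "| lowest HEP:", paste(attr(x, "min_hep_subtasks"), collapse = ", "), "\n")
  }
  invisible(x)
}
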