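#' Performance shaping factor taxonomy
#'
#' The taxonomy is a flat table of factors (subPSFs), each belonging to one
#' of the three PSF categories (`personal`, `job`, `organization`) and
#' carrying a definition and an in-category weight. The bundled default —
#' `load_taxonomy("default")` — is the emergency-department medication
#' study's taxonomy: 17 factors (5 personal, 6 job, 6 organization) with
#' the fuzzy-AHP weights of that study's expert panel (each category's
#' weights sum to 1 at the printed precision). Those weights are a
#' fixture: the panel's pairwise judgments were never published, so they
#' validate only against normalisation invariants, not recomputation.
#'
#' @param category,subpsf,definition,weight equal-length vectors describing
#'   the factors.
#' @return A data frame of class `psf_taxonomy`.
#' @export
psf_taxonomy <- function(category, subpsf, definition, weight) {
  out <- data.frame(category = as.character(category),
                    subpsf = as.character(subpsf),
                    definition = as.character(definition),
                    weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  bad_cat <- setdiff(unique(out$category), c("personal", "job", "organization"))
  if (length(bad_cat)) {
    stop("unknown PSF category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(out$subpsf)) {
    stop("duplicate factor label: ",
         out$subpsf[anyDuplicated(out$subpsf)], call. = FALSE)
  }
  if (any(out$weight < 0) || any(out$weight > 1)) {
    stop("factor weights must lie in [0, 1]", call. = FALSE)
  }
  sums <- tapply(out$weight, out$category, sum)
  off <- sums[abs(sums - 1) > 1e-3 + 1e-9]  # printed weights legitimately sum to 0.999
  if (length(off)) {
    stop("weights in category '", names(off)[1L], "' sum to ",
         format(off[[1L]]), ", expected 1 (within 1e-3)", call. = FALSE)
  }
  class(out) <- c("psf_taxonomy", "data.frame")
  out
}

#' @export
print.psf_taxonomy <- function(x, ...) {
  cat("<psf_taxonomy> ", nrow(x), " factors in ",
      length(unique(x$category)), " categories\n", sep = "")
  for (cat_ in unique(x$category)) {
    sub <- x[x$category == cat_, ]
    cat(" ", cat_, ":\n")
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-34s %.3f\n", sub$subpsf[i], sub$weight[i]))
    }
  }
  invisible(x)
}

#' @rdname psf_taxonomy
#' @param taxonomy a `psf_taxonomy`.
#' @param cat category label.
#' @return `taxonomy_weights()`: named weight vector of one category.
#' @export
taxonomy_weights <- function(taxonomy, cat) {
  sub <- taxonomy[taxonomy$category == cat, ]
  if (nrow(sub) == 0L) stop("no factors in category '", cat, "'", call. = FALSE)
  setNames(sub$weight, sub$subpsf)
}

default_path <- function(file) {
  system.file("extdata", file, package = "fuzzyslim", mustWork = TRUE)
}

#' Read or write a PSF taxonomy
#'
#' The on-disk form is YAML: one key per category, each a list of factor
#' records with `subpsf`, `definition` and `weight` fields. Loading
#' validates category names, label uniqueness and per-category weight sums
#' (tolerance 1e-3); a violated invariant rejects the whole file.
#' `save_taxonomy()` round-trips bit-identically through `load_taxonomy()`.
#'
#' @param path a file path, or `"default"` for the bundled
#'   emergency-department taxonomy.
#' @param taxonomy a [psf_taxonomy()].
#' @return `load_taxonomy()` returns a `psf_taxonomy`; `save_taxonomy()`
#'   returns `path` invisibly.
#' @examples
#' tax <- load_taxonomy("default")
#' taxonomy_weights(tax, "job")
#' @export
load_taxonomy <- function(path = "default") {
  if (identical(path, "default")) path <- default_path("psf_taxonomy.yaml")
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(names(raw), function(cat_) {
    recs <- raw[[cat_]]
    data.frame(category = cat_,
               subpsf = vapply(recs, function(r) as.character(r$subpsf), ""),
               definition = vapply(recs, function(r) as.character(r$definition), ""),
               weight = vapply(recs, function(r) as.numeric(r$weight), 0),
               stringsAsFactors = FALSE)
  }))
  psf_taxonomy(rows$category, rows$subpsf, rows$definition, rows$weight)
}

#' @rdname load_taxonomy
#' @export
save_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "psf_taxonomy"))
  out <- lapply(split(taxonomy, taxonomy$category), function(sub) {
    lapply(seq_len(nrow(sub)), function(i) {
      list(subpsf = sub$subpsf[i], definition = sub$definition[i],
           weight = sub$weight[i])
    })
  })
  # keep category order stable
  out <- out[intersect(unique(taxonomy$category), names(out))]
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Hierarchical task analysis
#'
#' An ordered list of tasks, each decomposed into subtasks with dotted
#' decimal ids (`"2.4"` is subtask 4 of task 2). The bundled default is
#' the emergency-department medication process: 5 tasks, 31 subtasks, from
#' patient admission through medication administration.
#'
#' @param task_id,task,subtask_id,subtask equal-length vectors (one row
#'   per subtask; `task` repeats the parent task's title).
#' @return A data frame of class `task_analysis`.
#' @export
task_analysis <- function(task_id, task, subtask_id, subtask) {
  out <- data.frame(task_id = as.character(task_id), task = as.character(task),
                    subtask_id = as.character(subtask_id),
                    subtask = as.character(subtask), stringsAsFactors = FALSE)
  if (anyDuplicated(out$subtask_id)) {
    stop("duplicate subtask id: ",
         out$subtask_id[anyDuplicated(out$subtask_id)], call. = FALSE)
  }
  ok <- startsWith(out$subtask_id, paste0(out$task_id, "."))
  if (any(!ok)) {
    stop("subtask id '", out$subtask_id[which(!ok)[1L]],
         "' is not numbered under task '", out$task_id[which(!ok)[1L]], "'",
         call. = FALSE)
  }
  class(out) <- c("task_analysis", "data.frame")
  out
}

#' @export
print.task_analysis <- function(x, ...) {
  cat("<task_analysis> ", length(unique(x$task_id)), " tasks, ",
      nrow(x), " subtasks\n", sep = "")
  for (tid in unique(x$task_id)) {
    sub <- x[x$task_id == tid, ]
    cat(" ", tid, ". ", sub$task[1L], "\n", sep = "")
    for (i in seq_len(nrow(sub))) {
      cat("    ", sub$subtask_id[i], " ", sub$subtask[i], "\n", sep = "")
    }
  }
  invisible(x)
}
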