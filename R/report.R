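#' Render an assessment report
#'
#' Formats [assess()] results either as a human-readable text report (a
#' ranking by decreasing HEP followed by the per-subtask listing) or as CSV
#' lines that re-parse to identical values. Ordering is deterministic:
#' ranking ties are broken by subtask id.
#'
#' @param results a non-empty `hep_results` frame from [assess()].
#' @param format `"text"` or `"csv"`.
#' @param path optional file to write the lines to.
#' @return character vector of report lines, invisibly when `path` is
#'   given.
#' @export
render_report <- function(results, format = c("text", "csv"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(results, "hep_results"))
  if (nrow(results) == 0L) stop("nothing to report: empty results", call. = FALSE)
  ord <- order(-results$hep, results$subtask_id)
  if (format == "csv") {
    df <- as.data.frame(results)[c("subtask_id", "r_personal", "r_job",
                                   "r_organization", "sli", "hep")]
    lines <- c(paste(names(df), collapse = ","),
               vapply(seq_len(nrow(df)), function(i) {
                 paste(c(df$subtask_id[i],
                         format(c(df$r_personal[i], df$r_job[i],
                                  df$r_organization[i], df$sli[i], df$hep[i]),
                                digits = 15, trim = TRUE, scientific = FALSE)),
                       collapse = ",")
               }, ""))
  } else {
    head_fmt <- sprintf("%-10s %8s %8s %8s %8s %10s", "subtask", "R_P", "R_J",
                        "R_O", "SLI", "HEP")
    row_fmt <- function(i) {
      sprintf("%-10s %8.3f %8.3f %8.3f %8.4f %10.3e", results$subtask_id[i],
              results$r_personal[i], results$r_job[i],
              results$r_organization[i], results$sli[i], results$hep[i])
    }
    lines <- c("Human error probability assessment",
               sprintf("%d subtasks | highest HEP: %s | lowest HEP: %s",
                       nrow(results),
                       paste(attr(results, "max_hep_subtasks"), collapse = ", "),
                       paste(attr(results, "min_hep_subtasks"), collapse = ", ")),
               "", "Ranking (most error-prone first):", head_fmt,
               vapply(ord, row_fmt, ""),
               "", "Task-analysis order:", head_fmt,
               vapply(seq_len(nrow(results)), row_fmt, ""))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Reproduce the bundled emergency-department case study
#'
#' Loads the bundled taxonomy, task analysis and rating sheet and runs the
#' full assessment with the published category weights and the default
#' calibration (error-probability bounds `1e-4` and `1` over the SLI range
#' `[1, 9]`).
#'
#' @param published_weights use the published category weights (default);
#'   `FALSE` requires `weights`.
#' @param weights category weights used when `published_weights = FALSE`.
#' @return An `hep_results` frame (see [assess()]).
#' @examples
#' res <- reproduce_case_study()
#' attr(res, "max_hep_subtasks")  # "2.4"
#' @export
reproduce_case_study <- function(published_weights = TRUE, weights = NULL) {
  tasks <- load_task_analysis("default")
  sheet <- load_ratings("default", tasks)
  tax <- load_taxonomy("default")
  w <- if (published_weights) published_category_weights() else weights
  if (is.null(w)) stop("weights required when published_weights = FALSE", call. = FALSE)
  assess(tasks, sheet, tax, w, slim_calibration())
}
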