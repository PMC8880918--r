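#' Rating sheet
#'
#' Long-format ratings for the subtasks of a task analysis. Each row rates
#' either one PSF category directly (`level = "category"`, `name` one of
#' `personal` / `job` / `organization`) or one factor
#' (`level = "subpsf"`, `name` a taxonomy factor label) on the 1 (worst
#' situation) to 9 (best situation) scale. A subtask must be rated on one
#' level only.
#'
#' @param subtask_id,level,name,rating equal-length vectors.
#' @return A data frame of class `rating_sheet`.
#' @export
rating_sheet <- function(subtask_id, level, name, rating) {
  out <- data.frame(subtask_id = as.character(subtask_id),
                    level = as.character(level), name = as.character(name),
                    rating = as.numeric(rating), stringsAsFactors = FALSE)
  bad <- which(!out$level %in% c("category", "subpsf"))
  if (length(bad)) {
    stop("row ", bad[1L], ": level must be 'category' or 'subpsf', got '",
         out$level[bad[1L]], "'", call. = FALSE)
  }
  bad <- which(!is.finite(out$rating) | out$rating < 1 | out$rating > 9)
  if (length(bad)) {
    stop("row ", bad[1L], ": rating ", format(out$rating[bad[1L]]),
         " outside [1, 9] for subtask ", out$subtask_id[bad[1L]], call. = FALSE)
  }
  dup <- duplicated(out[c("subtask_id", "name")])
  if (any(dup)) {
    stop("row ", which(dup)[1L], ": duplicate rating for subtask ",
         out$subtask_id[which(dup)[1L]], ", '", out$name[which(dup)[1L]], "'",
         call. = FALSE)
  }
  class(out) <- c("rating_sheet", "data.frame")
  out
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a task analysis or rating sheet
#'
#' `load_task_analysis()` reads a CSV with columns `task_id`, `task`,
#' `subtask_id`, `subtask`; `load_ratings()` reads the long rating format
#' (`subtask_id`, `level`, `name`, `rating`). With `path = "default"` the
#' bundled emergency-department case study is returned: 31 subtasks, each
#' rated at category level with that study's printed `R_P` / `R_J` / `R_O`
#' values. Loaders validate everything up front and reject the whole file
#' naming the first offending record; there are no partial loads.
#'
#' @param path a CSV path or `"default"`.
#' @param tasks optional [task_analysis()]; when given, every rated
#'   subtask id must exist in it.
#' @return A [task_analysis()] or [rating_sheet()].
#' @examples
#' tasks <- load_task_analysis("default")
#' ratings <- load_ratings("default", tasks)
#' @export
load_task_analysis <- function(path = "default") {
  if (identical(path, "default")) path <- default_path("task_analysis.csv")
  df <- read_csv_strict(path, c("task_id", "task", "subtask_id", "subtask"))
  task_analysis(df$task_id, df$task, df$subtask_id, df$subtask)
}

#' @rdname load_task_analysis
#' @export
load_ratings <- function(path = "default", tasks = NULL) {
  if (identical(path, "default")) path <- default_path("case_study_ratings.csv")
  df <- read_csv_strict(path, c("subtask_id", "level", "name", "rating"))
  sheet <- rating_sheet(df$subtask_id, df$level, df$name, df$rating)
  if (!is.null(tasks)) {
    bad <- which(!sheet$subtask_id %in% tasks$subtask_id)
    if (length(bad)) {
      stop(path, " row ", bad[1L], ": subtask id '", sheet$subtask_id[bad[1L]],
           "' not present in the task analysis", call. = FALSE)
    }
  }
  sheet
}

#' Read panel, opinion and judgment files
#'
#' `load_panel()` reads expert profiles (`id`, `experience`, `education`,
#' `relevancy`). `load_opinions()` reads linguistic importance judgments
#' (`item`, `expert`, `term`) into one [opinion_set()] per item, keeping
#' the file's item order. `load_judgments()` reads pairwise comparison
#' judgments (`category`, `criterion_a`, `criterion_b`, `term`, optional
#' `direction`) and returns them split by category, ready for
#' [build_matrix()].
#'
#' @param path CSV path.
#' @return See details.
#' @export
load_panel <- function(path) {
  df <- read_csv_strict(path, c("id", "experience", "education", "relevancy"))
  expert_profiles(df$id, df$experience, df$education, df$relevancy)
}

#' @rdname load_panel
#' @export
load_opinions <- function(path) {
  df <- read_csv_strict(path, c("item", "expert", "term"))
  items <- unique(df$item)
  sets <- lapply(items, function(it) {
    sub <- df[df$item == it, ]
    opinion_set(it, setNames(as.list(sub$term), sub$expert))
  })
  names(sets) <- items
  sets
}

#' @rdname load_panel
#' @export
load_judgments <- function(path) {
  df <- read_csv_strict(path, c("category", "criterion_a", "criterion_b", "term"))
  if (is.null(df$direction)) df$direction <- "a_over_b"
  split(df[c("criterion_a", "criterion_b", "term", "direction")], df$category)
}
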