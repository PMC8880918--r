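#' Linguistic scales
#'
#' A linguistic scale maps elicitation terms to fuzzy numbers. Two defaults
#' ship with the package:
#'
#' * `ahp_scale()` — the five-term importance-ratio scale used in the fuzzy
#'   pairwise comparisons ("Equal importance" (1,1,1) up to "Very much more
#'   importance" (2.5,3,3.5)).
#' * `fmagdm_scale()` — a seven-term triangular scale on `[0, 1]` for the
#'   panel's PSF-importance judgments. This scale is a package default, not
#'   taken from any published elicitation form; replace it with
#'   `linguistic_scale()` or `load_scale()` to mirror a study's own
#'   membership functions.
#'
#' @param terms named list mapping term labels to [fuzzy_number()] objects
#'   (plain numeric vectors are converted).
#' @return An object of class `linguistic_scale`: named list of fuzzy
#'   numbers with a `universe` attribute (range of all breakpoints).
#' @examples
#' ahp_scale()
#' scale_universe(fmagdm_scale())   # c(0, 1)
#' @export
linguistic_scale <- function(terms) {
  if (!is.list(terms) || length(terms) < 2L ||
      is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("a linguistic scale is a named list of at least two terms", call. = FALSE)
  }
  if (anyDuplicated(names(terms))) {
    stop("duplicate term labels in linguistic scale", call. = FALSE)
  }
  terms <- lapply(terms, as_fuzzy)
  universe <- range(unlist(lapply(terms, unclass)))
  structure(terms, universe = universe, class = "linguistic_scale")
}

#' @rdname linguistic_scale
#' @export
ahp_scale <- function() {
  linguistic_scale(list(
    "Equal importance"          = c(1, 1, 1),
    "A little more importance"  = c(1, 1.5, 2),
    "Relatively more importance" = c(1.5, 2, 2.5),
    "Much more importance"      = c(2, 2.5, 3),
    "Very much more importance" = c(2.5, 3, 3.5)
  ))
}

#' @rdname linguistic_scale
#' @export
fmagdm_scale <- function() {
  linguistic_scale(list(
    "Very low"    = c(0, 0, 0.1),
    "Low"         = c(0, 0.1, 0.3),
    "Fairly low"  = c(0.1, 0.3, 0.5),
    "Medium"      = c(0.3, 0.5, 0.7),
    "Fairly high" = c(0.5, 0.7, 0.9),
    "High"        = c(0.7, 0.9, 1),
    "Very high"   = c(0.9, 1, 1)
  ))
}

#' @rdname linguistic_scale
#' @param scale a `linguistic_scale`.
#' @export
scale_universe <- function(scale) {
  stopifnot(inherits(scale, "linguistic_scale"))
  attr(scale, "universe")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("<linguistic_scale> ", length(x), " terms on [",
      paste(format(attr(x, "universe")), collapse = ", "), "]\n", sep = "")
  for (nm in names(x)) cat("  ", format(nm, width = 28), format(x[[nm]]), "\n")
  invisible(x)
}

# resolve a term label (or raw points) against a scale
scale_term <- function(scale, term) {
  if (is_fuzzy_number(term)) return(term)
  if (is.numeric(term)) return(fuzzy_number(term))
  if (!term %in% names(scale)) {
    stop("unknown linguistic term '", term, "'; scale offers: ",
         paste(names(scale), collapse = ", "), call. = FALSE)
  }
  scale[[term]]
}

#' Read or write a linguistic scale as YAML
#'
#' The on-disk form is a mapping from term label to the numeric breakpoint
#' list, e.g. `Medium: [0.3, 0.5, 0.7]`.
#'
#' @param path file path.
#' @param scale a [linguistic_scale()].
#' @return `load_scale()` returns a `linguistic_scale`; `save_scale()`
#'   returns `path` invisibly.
#' @export
load_scale <- function(path) {
  raw <- yaml::read_yaml(path)
  linguistic_scale(raw)
}

#' @rdname load_scale
#' @export
save_scale <- function(scale, path) {
  stopifnot(inherits(scale, "linguistic_scale"))
  out <- lapply(scale, function(f) as.numeric(unclass(f)))
  yaml::write_yaml(out, path)
  invisible(path)
}
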