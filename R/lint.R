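#' Validation findings ("lints")
#'
#' A lint is a machine-generated finding about a name: an `error` (the name
#' is wrong or inconsistent with the reference), a `warning` (discouraged
#' style that remains legal), or `info` (a normalization or note). Lints are
#' stored as rows of a data frame so that findings from several names can be
#' stacked and summarized.
#'
#' @param severity one of `"error"`, `"warning"`, `"info"`.
#' @param code stable machine-readable rule identifier (see
#'   [lint_codes()]).
#' @param message human-readable description.
#' @param start,end 1-based character span in the source text (`NA` when the
#'   finding applies to the whole name).
#' @param suggestion replacement text, or `NA` when none is offered.
#' @return a one-row data frame of class `pomb_lints`.
#' @export
new_lint <- function(severity, code, message, start = NA_integer_,
                     end = NA_integer_, suggestion = NA_character_) {
  stopifnot(severity %in% c("error", "warning", "info"))
  structure(
    data.frame(
      severity = severity, code = code, message = message,
      start = as.integer(start), end = as.integer(end),
      suggestion = suggestion, stringsAsFactors = FALSE
    ),
    class = c("pomb_lints", "data.frame")
  )
}

#' @rdname new_lint
#' @export
no_lints <- function() {
  structure(
    data.frame(
      severity = character(), code = character(), message = character(),
      start = integer(), end = integer(), suggestion = character(),
      stringsAsFactors = FALSE
    ),
    class = c("pomb_lints", "data.frame")
  )
}

bind_lints <- function(...) {
  xs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(xs) == 0) return(no_lints())
  structure(do.call(rbind, c(xs, make.row.names = FALSE)),
            class = c("pomb_lints", "data.frame"))
}

#' Enumerate the lint codes emitted by the package
#'
#' @return data frame with columns `code`, `severity`, `meaning`.
#' @export
lint_codes <- function() {
  read.delim(
    system.file("extdata", "lint_codes.tsv", package = "pombelint"),
    comment.char = "#", stringsAsFactors = FALSE
  )
}

#' @export
print.pomb_lints <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("no findings\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    span <- if (is.na(x$start[i])) "" else sprintf(" [%d-%d]", x$start[i], x$end[i])
    sug <- if (is.na(x$suggestion[i])) "" else sprintf(" -> %s", x$suggestion[i])
    cat(sprintf("%-7s %-24s %s%s%s\n", x$severity[i], x$code[i],
                x$message[i], span, sug))
  }
  invisible(x)
}

# Conditions -------------------------------------------------------------

# Hard failures carry a class distinguishing malformed syntax from text that
# matches the surface grammar but violates a semantic constraint (descending
# range, stop codon not last, ...). The regex recognizers cannot see semantic
# constraints, so agreement between the regex route and the parser route is
# defined over syntax: a semantic error still counts as "recognized".
parse_error <- function(message, code = "parse_error", start = NA, end = NA,
                        semantic = FALSE) {
  cls <- c(
    if (semantic) "pombelint_semantic_error" else "pombelint_syntax_error",
    "pombelint_parse_error", "error", "condition"
  )
  stop(structure(
    class = cls,
    list(message = message, call = sys.call(-1), code = code,
         start = start, end = end)
  ))
}

is_parse_error <- function(x) inherits(x, "pombelint_parse_error")

#' @export
format.pombelint_parse_error <- function(x, ...) {
  span <- if (!is.na(x$start)) sprintf(" at characters %d-%d", x$start, x$end) else ""
  sprintf("[%s] %s%s", x$code, x$message, span)
}
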