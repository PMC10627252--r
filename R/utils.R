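# Low-level text scanning shared by the suffix and genotype parsers.
# All coordinates are 1-based character positions.

chars <- function(text) strsplit(text, "", fixed = TRUE)[[1]]

# Positions of `sep` characters at parenthesis/bracket depth zero.
top_level_positions <- function(text, seps) {
  cs <- chars(text)
  depth <- 0L
  out <- integer()
  for (i in seq_along(cs)) {
    c <- cs[i]
    if (c %in% c("(", "[")) depth <- depth + 1L
    else if (c %in% c(")", "]")) {
      depth <- depth - 1L
      if (depth < 0L) parse_error("unbalanced closing bracket",
                                  "unbalanced_bracket", i, i)
    } else if (depth == 0L && c %in% seps) out <- c(out, i)
  }
  if (depth != 0L) parse_error("unbalanced opening bracket",
                               "unbalanced_bracket", nchar(text), nchar(text))
  out
}

# Split text at top-level occurrences of single-character separators,
# returning pieces and the separator between consecutive pieces.
split_top_level <- function(text, seps) {
  pos <- top_level_positions(text, seps)
  if (length(pos) == 0) {
    return(list(pieces = text, seps = character()))
  }
  starts <- c(1L, pos + 1L)
  ends <- c(pos - 1L, nchar(text))
  pieces <- substring(text, starts, ends)
  list(pieces = pieces, seps = substring(text, pos, pos))
}

# Index of the ')' matching the '(' at `open`.
matching_paren <- function(text, open) {
  cs <- chars(text)
  depth <- 0L
  for (i in open:length(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    if (cs[i] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  parse_error("unbalanced parenthesis", "unbalanced_bracket", open, open)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
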