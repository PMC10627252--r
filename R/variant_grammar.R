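#' Allele variant-feature grammar
#'
#' Variants are described against the wild-type product sequence, at the
#' protein level for protein-coding genes (index 1 = initiator methionine)
#' and at the transcript level for RNA genes (DNA letters, T instead of U).
#' The suffix after the gene symbol encodes:
#'
#' * `+` — wild type; `Δ` — full deletion.
#' * `(1-35,40-700)` — partial deletion, retained residues;
#'   `Δ(114-120,150-200)` — partial deletion, removed residues.
#' * `-P114A,Q117A` — substitutions / insertions / deletion–insertions:
#'   replaced residues, index of the first replaced residue, replacement
#'   residues. An insertion repeats the flanking residue (`-P114PVAL`).
#' * `-CTD-Y1F(r1-r12)` — edits of the RNA-polymerase CTD tandem repeats,
#'   positions within the repeat unit, with optional repeat selectors
#'   (`rN`, `rN-rM`, `rN-rM-step`); the CTD block always comes last.
#' * anything else hyphen-joined — an allele "short name" (legal; the
#'   lesion is not machine readable).
#'
#' @name variant-grammar
NULL

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWY"
DNA_LETTERS <- "ACGT"

product_alphabet <- function(product_kind) {
  switch(product_kind,
         protein = AA_LETTERS,
         rna = DNA_LETTERS,
         parse_error(sprintf("unknown product kind '%s'", product_kind)))
}

# Feature constructors ---------------------------------------------------

vf <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "pomb_feature")
}

vf_wild_type <- function() vf("wild_type")
vf_full_deletion <- function() vf("full_deletion")
vf_unknown <- function() vf("unknown")
vf_loss_of_function <- function() vf("loss_of_function")

vf_partial_deletion <- function(mode, ranges) {
  stopifnot(mode %in% c("removed", "retained"))
  vf("partial_deletion", mode = mode, ranges = ranges)
}

vf_edits <- function(edits) vf("edits", edits = edits)
vf_ctd <- function(items) vf("ctd", items = items)

vf_short_name <- function(text, sep = "-") {
  vf("short_name", text = text, sep = sep)
}

classify_edit <- function(replaced, replacement) {
  if (nchar(replaced) == 1 && nchar(replacement) > 1 &&
      startsWith(replacement, replaced)) {
    "insertion"
  } else if (replacement == "*" || endsWith(replacement, "*")) {
    "nonsense"
  } else if (nchar(replaced) == nchar(replacement)) {
    "substitution"
  } else {
    "deletion_insertion"
  }
}

new_edit <- function(replaced, position, replacement) {
  structure(
    list(replaced = replaced, position = as.integer(position),
         replacement = replacement,
         kind = classify_edit(replaced, replacement)),
    class = "pomb_edit"
  )
}

# Range algebra -----------------------------------------------------------

as_range_matrix <- function(ranges) {
  if (is.matrix(ranges)) {
    m <- ranges
  } else if (is.list(ranges)) {
    m <- do.call(rbind, lapply(ranges, function(r) as.integer(r[1:2])))
  } else {
    m <- matrix(as.integer(ranges), ncol = 2, byrow = TRUE)
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

validate_ranges <- function(m, where = "range") {
  if (nrow(m) == 0) parse_error("empty range list", semantic = TRUE)
  if (any(m[, 1] < 1L)) {
    parse_error("residue positions are 1-based", "out_of_range", semantic = TRUE)
  }
  if (any(m[, 1] > m[, 2])) {
    parse_error(sprintf("descending %s (start > end)", where),
                "descending_range", semantic = TRUE)
  }
  if (nrow(m) > 1) {
    if (any(diff(m[, 1]) <= 0) || any(m[-1, 1] <= m[-nrow(m), 2])) {
      parse_error(sprintf("%ss must be ascending and non-overlapping", where),
                  "descending_range", semantic = TRUE)
    }
  }
  m
}

#' Complement a set of residue ranges within a product of known length
#'
#' Converts between the retained-residue and removed-residue descriptions
#' of the same partial deletion: the retained ranges are the complement of
#' the deleted ranges within `[1, length]`, and vice versa. The operation
#' is an involution at fixed length.
#'
#' @param ranges matrix/list of 1-based inclusive `start`,`end` pairs,
#'   sorted and non-overlapping.
#' @param length product length in residues.
#' @return integer matrix of complementary ranges (possibly zero rows).
#' @examples
#' complement_ranges(rbind(c(1, 113)), 731) # 114-731
#' @export
complement_ranges <- function(ranges, length) {
  m <- validate_ranges(as_range_matrix(ranges))
  length <- as.integer(length)
  if (any(m[, 2] > length)) {
    parse_error(sprintf("range end %d exceeds product length %d",
                        max(m[, 2]), length), "out_of_range", semantic = TRUE)
  }
  starts <- c(1L, unname(m[, 2]) + 1L)
  ends <- c(unname(m[, 1]) - 1L, length)
  keep <- starts <= ends
  out <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

# CTD selectors -----------------------------------------------------------

new_ctd_selector <- function(start, end = NA_integer_, step = 1L) {
  list(start = as.integer(start), end = as.integer(end),
       step = as.integer(step))
}

validate_ctd_selector <- function(s) {
  if (s$start < 1L) parse_error("repeat indices start at r1",
                                "bad_repeat_index", semantic = TRUE)
  if (s$step < 1L) parse_error("selector step must be at least 1",
                               "bad_repeat_index", semantic = TRUE)
  if (!is.na(s$end) && s$end < s$start) {
    parse_error("descending repeat range", "bad_repeat_index", semantic = TRUE)
  }
  if (is.na(s$end) && s$step != 1L) {
    parse_error("a step needs an explicit repeat range", "bad_repeat_index",
                semantic = TRUE)
  }
  invisible(s)
}

#' Expand CTD repeat selectors into the set of repeat indices
#'
#' @param selectors list of selectors (`start`, `end`, `step`), e.g. from a
#'   parsed `(r1-r29-2)` group; an empty list selects every repeat.
#' @param n_repeats number of repeats in the reference CTD.
#' @return sorted integer vector of repeat indices.
#' @examples
#' expand_ctd_selectors(list(list(start = 1, end = 29, step = 2)), 29)
#' @export
expand_ctd_selectors <- function(selectors, n_repeats) {
  n_repeats <- as.integer(n_repeats)
  if (length(selectors) == 0) return(seq_len(n_repeats))
  idx <- integer()
  for (s in selectors) {
    end <- if (is.na(s$end %||% NA)) s$start else s$end
    step <- as.integer(s$step %||% 1L)
    if (max(s$start, end) > n_repeats) {
      parse_error(sprintf("repeat r%d exceeds the %d reference repeats",
                          max(s$start, end), n_repeats),
                  "bad_repeat_index", semantic = TRUE)
    }
    idx <- c(idx, seq.int(s$start, end, by = step))
  }
  sort(unique(as.integer(idx)))
}

# Parsing -----------------------------------------------------------------

RANGES_BODY_RE <- "^\\d+-\\d+(,\\d+-\\d+)*$"
EDIT_RE <- "^([A-Za-z]+)([0-9]+)([A-Za-z*]+)$"

# syntax only; semantic constraints (ascending, non-overlapping) are
# validated once the whole suffix has been consumed
parse_range_group <- function(inner) {
  if (!grepl(RANGES_BODY_RE, inner)) {
    parse_error(sprintf("malformed residue range '%s'", inner))
  }
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  as_range_matrix(lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
}

parse_edit_token <- function(token, alphabet) {
  m <- regexec(EDIT_RE, token)
  if (m[[1]][1] == -1) parse_error(sprintf("malformed edit '%s'", token))
  g <- regmatches(token, m)[[1]]
  replaced <- g[2]; position <- g[3]; replacement <- g[4]
  cls <- sprintf("^[%s]+$", alphabet)
  if (!grepl(cls, replaced)) {
    parse_error(sprintf("'%s' contains letters outside the product alphabet",
                        replaced))
  }
  if (!grepl(sprintf("^[%s*]+$", alphabet), replacement)) {
    parse_error(sprintf("'%s' contains letters outside the product alphabet",
                        replacement))
  }
  new_edit(replaced, position, replacement)
}

validate_edit <- function(e) {
  if (grepl("\\*", substr(e$replacement, 1, nchar(e$replacement) - 1))) {
    parse_error("the stop codon '*' may only end a replacement",
                "stop_not_last", semantic = TRUE)
  }
  if (e$position < 1L) {
    parse_error("residue positions are 1-based", "out_of_range",
                semantic = TRUE)
  }
  invisible(e)
}

check_edit_overlap <- function(edits) {
  if (length(edits) < 2) return(invisible())
  spans <- t(vapply(edits, function(e) {
    c(e$position, e$position + nchar(e$replaced) - 1L)
  }, integer(2)))
  o <- order(spans[, 1])
  spans <- spans[o, , drop = FALSE]
  if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
    parse_error("edits touch the same reference residues",
                "overlapping_edits", semantic = TRUE)
  }
  invisible()
}

parse_ctd_selector_group <- function(inner) {
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0 || any(!nzchar(parts))) {
    parse_error(sprintf("malformed repeat selector '(%s)'", inner))
  }
  lapply(parts, function(p) {
    m <- regexec("^r([0-9]+)(-r([0-9]+)(-([0-9]+))?)?$", p)
    if (m[[1]][1] == -1) {
      parse_error(sprintf("malformed repeat selector '%s'", p))
    }
    g <- regmatches(p, m)[[1]]
    new_ctd_selector(
      start = g[2],
      end = if (nzchar(g[4])) g[4] else NA_integer_,
      step = if (nzchar(g[6])) g[6] else 1L
    )
  })
}

#' Parse the CTD block of an allele suffix
#'
#' `text` is the portion after `"CTD-"`: comma-separated items, each an
#' in-repeat edit (`Y1F`), an in-repeat partial deletion (`Δ(2-4)`), or a
#' repeat deletion `Δ`, with an optional repeat selector (`(r1-r29-2)`).
#'
#' @param text CTD block text.
#' @param product_kind `"protein"` (the CTD is a protein domain).
#' @param validate check semantic constraints (set `FALSE` to defer them,
#'   as the full-suffix parser does until the whole suffix is consumed).
#' @return list of CTD edit items.
#' @export
parse_ctd_suffix <- function(text, product_kind = "protein", validate = TRUE) {
  alphabet <- product_alphabet(product_kind)
  if (!nzchar(text)) parse_error("empty CTD block")
  pieces <- split_top_level(text, ",")$pieces
  if (any(!nzchar(pieces)) || endsWith(text, ",")) {
    parse_error("empty CTD item (stray comma)")
  }
  items <- lapply(pieces, function(piece) {
    selectors <- list()
    # optional trailing (r...) selector
    m <- regexpr("\\(r[^()]*\\)$", piece)
    if (m != -1) {
      inner <- substr(piece, m + 1L, nchar(piece) - 1L)
      selectors <- parse_ctd_selector_group(inner)
      piece <- substr(piece, 1L, m - 1L)
    }
    if (piece == "Δ") {
      item <- list(op = "delete_repeat", edit = NULL, ranges = NULL)
    } else if (startsWith(piece, "Δ(")) {
      if (!endsWith(piece, ")")) parse_error("malformed CTD deletion group")
      item <- list(op = "partial_deletion",
                   ranges = parse_range_group(
                     substr(piece, 3L, nchar(piece) - 1L)),
                   edit = NULL)
    } else if (nzchar(piece)) {
      item <- list(op = "edit", edit = parse_edit_token(piece, alphabet),
                   ranges = NULL)
    } else {
      parse_error("CTD selector without a mutation")
    }
    item$selectors <- selectors
    item
  })
  if (validate) validate_ctd_items(items)
  items
}

validate_ctd_items <- function(items) {
  for (item in items) {
    lapply(item$selectors, validate_ctd_selector)
    if (item$op == "edit") validate_edit(item$edit)
    if (item$op == "partial_deletion") {
      validate_ranges(item$ranges, "CTD deletion range")
    }
  }
  invisible(items)
}

validate_variant_features <- function(features) {
  for (f in features) {
    if (f$type == "partial_deletion") validate_ranges(f$ranges)
    if (f$type == "edits") {
      lapply(f$edits, validate_edit)
      check_edit_overlap(f$edits)
    }
    if (f$type == "ctd") validate_ctd_items(f$items)
  }
  invisible(features)
}

# Structured parse of a suffix; hard error when the text is not in the
# structured grammar (callers may fall back to a short name).
parse_variant_suffix_structured <- function(text, product_kind = "protein") {
  alphabet <- product_alphabet(product_kind)
  if (grepl("[[:space:]]", text)) {
    parse_error("spaces are not allowed in allele names", "space_in_allele")
  }
  if (text == "+") return(list(vf_wild_type()))
  if (text == "Δ") return(list(vf_full_deletion()))
  features <- list()
  rest <- text

  take_paren_group <- function(rest) {
    close <- matching_paren(rest, regexpr("(", rest, fixed = TRUE))
    list(inner = substr(rest, regexpr("(", rest, fixed = TRUE) + 1L, close - 1L),
         rest = substr(rest, close + 1L, nchar(rest)))
  }

  # optional partial deletion first
  if (startsWith(rest, "Δ(")) {
    g <- take_paren_group(rest)
    features <- c(features, list(
      vf_partial_deletion("removed", parse_range_group(g$inner))))
    rest <- g$rest
  } else if (startsWith(rest, "(")) {
    g <- take_paren_group(rest)
    features <- c(features, list(
      vf_partial_deletion("retained", parse_range_group(g$inner))))
    rest <- g$rest
  }

  # optional edits: -E1,E2,...  stopping before a -CTD- block
  if (nzchar(rest) && startsWith(rest, "-") && !startsWith(rest, "-CTD-")) {
    body <- substr(rest, 2L, nchar(rest))
    ctd_at <- regexpr("-CTD-", body, fixed = TRUE)
    edit_text <- if (ctd_at == -1) body else substr(body, 1L, ctd_at - 1L)
    rest <- if (ctd_at == -1) "" else substr(body, ctd_at, nchar(body))
    tokens <- strsplit(edit_text, ",", fixed = TRUE)[[1]]
    if (length(tokens) == 0 || any(!nzchar(tokens)) ||
        endsWith(edit_text, ",")) {
      parse_error("malformed edit list")
    }
    edits <- lapply(tokens, parse_edit_token, alphabet = alphabet)
    features <- c(features, list(vf_edits(edits)))
  }

  # optional CTD block, always last
  if (startsWith(rest, "-CTD-")) {
    features <- c(features, list(
      vf_ctd(parse_ctd_suffix(substr(rest, 6L, nchar(rest)), product_kind,
                              validate = FALSE))))
    rest <- ""
  }

  if (nzchar(rest) || length(features) == 0) {
    parse_error(sprintf("'%s' does not match the variant grammar", text))
  }
  # surface syntax fully consumed; now enforce the semantic constraints
  validate_variant_features(features)
  features
}

SHORT_NAME_RE <- "^-[A-Za-z0-9_]+$"
TRUNCATION_RE <- "^Δ?(N|C)(term)?$"

#' Parse an allele variant-feature suffix
#'
#' Parses the portion of an allele name after the gene symbol into
#' structured variant features. Text that does not match the structured
#' grammar but is a legal hyphen-joined letters/digits token is returned
#' as a `short_name` feature with an info-level note; an underscore inside
#' a short name is an error-level finding (underscores are not allowed).
#'
#' @param text suffix text (`"+"`, `"Δ"`, `"Δ(114-120)"`, `"-P114A"`, ...).
#' @param product_kind `"protein"` or `"rna"` (RNA variants use DNA letters).
#' @return list of features, with any findings in `attr(, "lints")`.
#' @examples
#' parse_variant_suffix("Δ(114-120,150-200)")
#' parse_variant_suffix("-P114A,Q117A")
#' parse_variant_suffix("-35") # short name
#' @export
parse_variant_suffix <- function(text, product_kind = "protein") {
  res <- tryCatch(
    list(features = parse_variant_suffix_structured(text, product_kind),
         lints = no_lints()),
    pombelint_syntax_error = function(e) NULL
  )
  if (!is.null(res)) {
    return(structure(res$features, lints = res$lints))
  }
  # short-name fallback
  if (grepl(SHORT_NAME_RE, text)) {
    name <- substr(text, 2L, nchar(text))
    lints <- new_lint("info", "short_name",
                      sprintf("allele short name '%s' (lesion not machine readable)", name))
    if (grepl("_", name, fixed = TRUE)) {
      lints <- bind_lints(lints, new_lint(
        "error", "underscore_in_name",
        "underscores are not allowed in allele variant short names",
        suggestion = gsub("_", "-", name, fixed = TRUE)
      ))
    }
    return(structure(list(vf_short_name(name)), lints = lints))
  }
  if (grepl("^Δ[A-Za-z0-9]+$", text)) {
    # truncation-style names such as (Delta)Nterm: legal short name, discouraged
    name <- text
    lints <- new_lint("warning", "truncation_name",
                      "truncation short names (ΔN/ΔC style) are discouraged")
    return(structure(list(vf_short_name(name, sep = "")), lints = lints))
  }
  parse_error(sprintf("'%s' is not a valid allele suffix", text))
}

# TRUE when text is in the structured surface grammar (syntactically);
# semantic violations still count as recognized. Used for the
# regex-vs-parser agreement property.
recognize_variant_suffix <- function(text, product_kind = "protein") {
  tryCatch({
    parse_variant_suffix_structured(text, product_kind)
    TRUE
  },
  pombelint_semantic_error = function(e) TRUE,
  pombelint_syntax_error = function(e) FALSE)
}

# Serialization ------------------------------------------------------------

serialize_ranges <- function(m) {
  paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
}

serialize_edit <- function(e) sprintf("%s%d%s", e$replaced, e$position, e$replacement)

serialize_selector <- function(s) {
  if (is.na(s$end)) sprintf("r%d", s$start)
  else if (s$step == 1L) sprintf("r%d-r%d", s$start, s$end)
  else sprintf("r%d-r%d-%d", s$start, s$end, s$step)
}

serialize_ctd_item <- function(item) {
  head <- switch(item$op,
    delete_repeat = "Δ",
    partial_deletion = sprintf("Δ(%s)", serialize_ranges(item$ranges)),
    edit = serialize_edit(item$edit)
  )
  if (length(item$selectors) > 0) {
    head <- sprintf("%s(%s)", head,
                    paste(vapply(item$selectors, serialize_selector, ""),
                          collapse = ","))
  }
  head
}

#' Serialize variant features back to guideline surface form
#'
#' Inverse of [parse_variant_suffix()]: `parse(serialize(f))` recovers `f`
#' and `serialize(parse(text))` recovers canonical `text`. A CTD block not
#' in final position is an error (the CTD block always goes last).
#'
#' @param features list of features as returned by [parse_variant_suffix()].
#' @return the suffix text.
#' @export
serialize_variant_features <- function(features) {
  if (length(features) == 0) return("")
  types <- vapply(features, function(f) f$type, "")
  ctd_pos <- which(types == "ctd")
  if (length(ctd_pos) > 1 ||
      (length(ctd_pos) == 1 && ctd_pos != length(features))) {
    parse_error("the CTD block must come last", semantic = TRUE)
  }
  paste0(vapply(features, function(f) {
    switch(f$type,
      wild_type = "+",
      full_deletion = "Δ",
      unknown = "?",
      loss_of_function = "-",
      partial_deletion = sprintf(
        "%s(%s)", if (f$mode == "removed") "Δ" else "",
        serialize_ranges(f$ranges)),
      edits = paste0("-", paste(vapply(f$edits, serialize_edit, ""),
                                collapse = ",")),
      ctd = paste0("-CTD-", paste(vapply(f$items, serialize_ctd_item, ""),
                                  collapse = ",")),
      short_name = paste0(f$sep, f$text),
      parse_error(sprintf("unknown feature type '%s'", f$type))
    )
  }, ""), collapse = "")
}
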