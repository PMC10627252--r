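#' Genotype and allele parsing
#'
#' A genotype is a space-separated list of locus entries, an optional
#' mating-type token (`h+`, `h-`, `h90`, `h?`) and optional replicating
#' plasmids in square brackets. Each allele name is a chain of components
#' joined by `-` (functionally linked) or `:` (adjacent, not functionally
#' linked), with at most one `::` marking the insertion locus, an optional
#' `@(...)` genomic anchor, `/` separating the two alleles of a diploid
#' locus, and `\` prefixing the provenance of foreign components.
#'
#' @name genotype-parsing
NULL

# Character normalization -------------------------------------------------

# Unicode lookalikes silently introduced by word processors, and the
# superscript letters/digits that cannot be stored in plain-text databases.
UNICODE_MAP <- c(
  "−" = "-",  # minus sign
  "–" = "-",  # en dash
  "—" = "-",  # em dash
  " " = " ",  # no-break space
  " " = " "   # thin space
)
SUPERSCRIPT_MAP <- c(
  "⁰" = "0", "¹" = "1", "²" = "2", "³" = "3",
  "⁴" = "4", "⁵" = "5", "⁶" = "6", "⁷" = "7",
  "⁸" = "8", "⁹" = "9",
  "ʳ" = "r", "ˢ" = "s", "ᵗ" = "t", "ᵈ" = "d",
  "⁺" = "+", "⁻" = "-"
)

ALLOWED_CHARS_RE <- "^[A-Za-z0-9 ?+/:.\\\\@()\\[\\]*,_Δ-]*$"

normalize_genotype_text <- function(text) {
  lints <- no_lints()
  cs <- chars(text)
  for (i in seq_along(cs)) {
    c <- cs[i]
    if (c %in% names(UNICODE_MAP)) {
      lints <- bind_lints(lints, new_lint(
        "info", "char_normalized",
        sprintf("U+%04X normalized to '%s'", utf8ToInt(c), UNICODE_MAP[[c]]),
        i, i, UNICODE_MAP[[c]]))
      cs[i] <- UNICODE_MAP[[c]]
    } else if (c %in% names(SUPERSCRIPT_MAP)) {
      lints <- bind_lints(lints, new_lint(
        "warning", "superscript",
        sprintf("superscript '%s' cannot be stored; flattened to '%s'",
                c, SUPERSCRIPT_MAP[[c]]),
        i, i, SUPERSCRIPT_MAP[[c]]))
      cs[i] <- SUPERSCRIPT_MAP[[c]]
    }
  }
  text <- paste(cs, collapse = "")
  if (!grepl(ALLOWED_CHARS_RE, text, perl = TRUE)) {
    bad <- regexpr("[^A-Za-z0-9 ?+/:.\\\\@()\\[\\]*,_Δ-]", text, perl = TRUE)
    parse_error(
      sprintf("character '%s' is not allowed (non-ASCII other than Δ, or a reserved symbol)",
              substr(text, bad, bad)),
      "forbidden_char", bad, bad)
  }
  list(text = text, lints = lints)
}

#' Tokenize a genotype string
#'
#' Splits on whitespace outside square brackets, classifying bracket
#' groups as plasmids. Unicode lookalikes (minus sign, dashes, no-break
#' space) are normalized with a recorded finding; superscript characters
#' are flattened with a warning; any other non-ASCII character (except
#' `Δ`) or a disallowed symbol is a hard error.
#'
#' @param text a genotype string.
#' @return list with `tokens` (data frame: `text`, `type`, `start`) and
#'   `lints`.
#' @export
tokenize_genotype <- function(text) {
  norm <- normalize_genotype_text(text)
  text <- norm$text
  cs <- chars(text)
  tokens <- list()
  buf_start <- NA_integer_
  depth_sq <- 0L
  i <- 1L
  flush <- function(end) {
    if (!is.na(buf_start) && end >= buf_start) {
      piece <- substr(text, buf_start, end)
      type <- if (startsWith(piece, "[")) "plasmid" else "word"
      if (type == "plasmid") {
        if (!endsWith(piece, "]")) {
          parse_error("unbalanced square bracket", "unbalanced_bracket",
                      buf_start, end)
        }
        piece <- substr(piece, 2, nchar(piece) - 1)
      }
      tokens[[length(tokens) + 1L]] <<- list(text = piece, type = type,
                                             start = buf_start)
    }
    buf_start <<- NA_integer_
  }
  while (i <= length(cs)) {
    c <- cs[i]
    if (c == "[") depth_sq <- depth_sq + 1L
    if (c == "]") {
      depth_sq <- depth_sq - 1L
      if (depth_sq < 0L) parse_error("unbalanced square bracket",
                                     "unbalanced_bracket", i, i)
    }
    if (c == " " && depth_sq == 0L) {
      flush(i - 1L)
    } else if (is.na(buf_start)) {
      buf_start <- i
    }
    i <- i + 1L
  }
  if (depth_sq != 0L) parse_error("unbalanced square bracket",
                                  "unbalanced_bracket", length(cs), length(cs))
  flush(length(cs))
  toks <- if (length(tokens) == 0) {
    data.frame(text = character(), type = character(), start = integer(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(text = vapply(tokens, `[[`, "", "text"),
               type = vapply(tokens, `[[`, "", "type"),
               start = vapply(tokens, `[[`, 1L, "start"),
               stringsAsFactors = FALSE)
  }
  list(tokens = toks, lints = norm$lints)
}

# Genomic anchors ----------------------------------------------------------

#' Parse a genomic anchor
#'
#' Anchors pin an insertion to exact coordinates on a chromosome sequence:
#' `@(<accession>:<left>_<right>ins)` for an insertion between two adjacent
#' nucleotides, or `@(<accession>:<start>_<end>delins)` for a
#' deletion–insertion spanning a range. Accessions are INSDC or RefSeq
#' sequence identifiers; coordinates are 1-based.
#'
#' @param text anchor text beginning `@(`.
#' @return list with `accession`, `start`, `end`, `kind`.
#' @examples
#' parse_genomic_anchor("@(CU329670.1:3571861_3571862ins)")
#' @export
parse_genomic_anchor <- function(text) {
  m <- regexec("^@\\(([A-Za-z0-9][A-Za-z0-9._]*):([0-9]+)_([0-9]+)(ins|delins)\\)$",
               text)
  if (m[[1]][1] == -1) {
    parse_error(sprintf("malformed genomic anchor '%s'", text))
  }
  g <- regmatches(text, m)[[1]]
  start <- as.integer(g[3]); end <- as.integer(g[4]); kind <- g[5]
  if (kind == "ins" && end != start + 1L) {
    parse_error("insertion flanks must be adjacent nucleotides",
                "descending_range", semantic = TRUE)
  }
  if (kind == "delins" && end <= start) {
    parse_error("deletion-insertion span must have start < end",
                "descending_range", semantic = TRUE)
  }
  structure(list(accession = g[2], start = start, end = end, kind = kind),
            class = "pomb_anchor")
}

serialize_anchor <- function(a) {
  sprintf("@(%s:%d_%d%s)", a$accession, a$start, a$end, a$kind)
}

# Components ---------------------------------------------------------------

new_component <- function(kind, ..., link = "") {
  structure(c(list(kind = kind, link = link), list(...)),
            class = "pomb_component")
}

SUBCOMPONENT_RE <- "^(P|T|CDS|5UTR|3UTR|intron[0-9]+)\\."
PROVENANCE_RE <- "^([A-Za-z0-9]+)\\\\"
TOKEN_RE <- "^[A-Za-z0-9]+"
CLASSIC_AT_RE <- "^[a-z]{3}[0-9]+"
TRANSCRIPT_AT_RE <- "^[a-z]{3}[0-9]+\\.[0-9]+"
SYSTEMATIC_AT_RE <- "^(SP|SJAG|SOCG|SPOG|SOMG)[A-Za-z0-9]+(\\.[0-9]+c?)?"

# characters that may legally follow a gene symbol inside an allele name
boundary_ok <- function(text, after) {
  after > nchar(text) ||
    substr(text, after, after) %in% c("+", "Δ", "(", "-", ":", "?",
                                      "_", ".", "@")
}

parser_state <- function(lexicon, genes) {
  list(lexicon = lexicon,
       genes = genes[order(-nchar(genes))],
       lints = new.env(parent = emptyenv()))
}

add_lint <- function(state, lint) {
  cur <- get0("lints", envir = state$lints, ifnotfound = no_lints())
  assign("lints", bind_lints(cur, lint), envir = state$lints)
}

state_lints <- function(state) {
  get0("lints", envir = state$lints, ifnotfound = no_lints())
}

# longest known-symbol / pattern match for a gene symbol at `pos`
match_gene_at <- function(text, pos, state) {
  remaining <- substring(text, pos)
  for (g in state$genes) {
    if (startsWith(remaining, g)) {
      # transcript-qualified form of a known symbol: gene.N
      tm <- regexpr("^\\.[0-9]+", substring(remaining, nchar(g) + 1L))
      if (tm == 1L &&
          boundary_ok(text, pos + nchar(g) + attr(tm, "match.length"))) {
        return(substr(remaining, 1, nchar(g) + attr(tm, "match.length")))
      }
      if (boundary_ok(text, pos + nchar(g))) return(g)
    }
  }
  for (re in c(TRANSCRIPT_AT_RE, CLASSIC_AT_RE, SYSTEMATIC_AT_RE)) {
    m <- regexpr(re, remaining)
    if (m == 1L) {
      len <- attr(m, "match.length")
      if (boundary_ok(text, pos + len)) return(substr(remaining, 1, len))
    }
  }
  NULL
}

token_resolves_as_element <- function(chunk, state) {
  if (!nzchar(chunk)) return(FALSE)
  if (startsWith(chunk, "(")) return(TRUE)
  if (grepl(PROVENANCE_RE, chunk)) return(TRUE)
  if (grepl(SUBCOMPONENT_RE, chunk)) return(TRUE)
  if (chunk %in% state$lexicon$token) return(TRUE)
  g <- match_gene_at(chunk, 1L, state)
  if (!is.null(g) && nchar(g) == nchar(chunk)) return(TRUE)
  FALSE
}

feature_category <- function(token, state) {
  hit <- match(token, state$lexicon$token)
  if (!is.na(hit)) state$lexicon$category[hit] else NA_character_
}

# parse one element starting at pos; returns list(component, pos)
scan_element <- function(text, pos, state) {
  remaining <- substring(text, pos)

  # linker or grouping parentheses
  if (startsWith(remaining, "(")) {
    close <- matching_paren(text, pos)
    inner <- substr(text, pos + 1L, close - 1L)
    comp <- if (grepl("^[A-Z]+$", inner)) {
      new_component("linker", residues = inner)
    } else {
      new_component("group", components = scan_chain(inner, state))
    }
    return(list(component = comp, pos = close + 1L))
  }

  # provenance prefix: <source>\<element>
  m <- regexec(PROVENANCE_RE, remaining)
  if (m[[1]][1] != -1) {
    prov <- regmatches(remaining, m)[[1]][2]
    inner_pos <- pos + nchar(prov) + 1L
    inner_rem <- substring(text, inner_pos)
    sm <- regexec(paste0(SUBCOMPONENT_RE, "([A-Za-z0-9]+)"), inner_rem)
    if (sm[[1]][1] != -1) {
      g <- regmatches(inner_rem, sm)[[1]]
      comp <- new_component("subcomponent", part = g[2], host = g[3],
                            provenance = prov)
      return(list(component = comp, pos = inner_pos + nchar(g[1])))
    }
    tm <- regexpr(TOKEN_RE, inner_rem)
    if (tm != 1L) parse_error("provenance prefix with no component",
                              start = pos, end = inner_pos)
    token <- substr(inner_rem, 1, attr(tm, "match.length"))
    comp <- new_component("feature", token = token,
                          category = feature_category(token, state) %||% "carried",
                          provenance = prov)
    return(list(component = comp, pos = inner_pos + nchar(token)))
  }

  # gene-structure subcomponent: P.act1, T.nmt1, CDS.prp22, 3UTR.prp22, ...
  sm <- regexec(paste0(SUBCOMPONENT_RE, "([A-Za-z0-9]+)"), remaining)
  if (sm[[1]][1] != -1) {
    g <- regmatches(remaining, sm)[[1]]
    comp <- new_component("subcomponent", part = g[2], host = g[3],
                          provenance = NA_character_)
    return(list(component = comp, pos = pos + nchar(g[1])))
  }

  # gene symbol plus variant suffix
  sym <- match_gene_at(text, pos, state)
  if (!is.null(sym)) {
    return(scan_gene_element(text, pos, sym, state))
  }

  # lexicon feature or unknown bare token
  tm <- regexpr(TOKEN_RE, remaining)
  if (tm == 1L) {
    token <- substr(remaining, 1, attr(tm, "match.length"))
    after <- pos + nchar(token)
    if (after <= nchar(text) && !substr(text, after, after) %in% c("-", ":")) {
      parse_error(sprintf("unexpected character '%s' after '%s'",
                          substr(text, after, after), token),
                  start = after, end = after)
    }
    category <- feature_category(token, state)
    if (is.na(category)) {
      category <- "unknown"
      add_lint(state, new_lint("info", "unknown_token",
                               sprintf("'%s' is not in the feature lexicon", token),
                               pos, after - 1L))
    }
    comp <- new_component("feature", token = token, category = category,
                          provenance = NA_character_)
    return(list(component = comp, pos = after))
  }

  parse_error(sprintf("cannot read an allele component at '%s'",
                      substr(remaining, 1, 12)), start = pos, end = pos)
}

scan_gene_element <- function(text, pos, sym, state) {
  transcript <- NA_integer_
  symbol <- sym
  if (grepl("^[a-z]{3}[0-9]+\\.[0-9]+$", sym)) {
    dot <- regexpr(".", sym, fixed = TRUE)
    symbol <- substr(sym, 1, dot - 1L)
    transcript <- as.integer(substr(sym, dot + 1L, nchar(sym)))
  }
  after_sym <- pos + nchar(sym)
  rest <- substring(text, after_sym)
  mk <- function(features, consumed, sep = NULL) {
    comp <- new_component("gene", symbol = symbol, transcript = transcript,
                          features = features)
    list(component = comp, pos = after_sym + consumed)
  }

  if (!nzchar(rest)) return(mk(list(), 0L))

  # unknown allele: gene?
  if (startsWith(rest, "?")) {
    if (nchar(rest) > 1L) {
      parse_error("'?' must end the allele name", start = after_sym + 1L,
                  end = after_sym + 1L)
    }
    return(mk(list(vf_unknown()), 1L))
  }

  # legacy underscore short name: gene_name (underscores are not allowed)
  um <- regexpr("^_[A-Za-z0-9_]+", rest)
  if (um == 1L) {
    chunk <- substr(rest, 2, attr(um, "match.length"))
    add_lint(state, new_lint(
      "error", "underscore_in_name",
      "underscores are not allowed in allele variant short names",
      after_sym + 1L, after_sym + attr(um, "match.length"),
      suggestion = paste0(symbol, "-", gsub("_", "-", chunk, fixed = TRUE))))
    f <- vf_short_name(chunk, sep = "_")
    return(mk(list(f), attr(um, "match.length")))
  }

  # legacy period short name: cut12.s11 (transcript numbers are digits only
  # and were consumed with the symbol)
  pm <- regexpr("^\\.[A-Za-z][A-Za-z0-9]*", rest)
  if (pm == 1L) {
    chunk <- substr(rest, 2, attr(pm, "match.length"))
    add_lint(state, new_lint(
      "warning", "period_separator",
      "legacy period separator in a short name; hyphens are recommended",
      after_sym + 1L, after_sym + attr(pm, "match.length"),
      suggestion = paste0(symbol, "-", chunk)))
    f <- vf_short_name(chunk, sep = ".")
    return(mk(list(f), attr(pm, "match.length")))
  }

  if (substr(rest, 1, 1) %in% c("-", ":") == FALSE ||
      startsWith(rest, "-")) {
    # candidate structured suffixes end before a top-level separator
    seps <- top_level_positions(rest, c("-", ":"))
    cut_ends <- sort(unique(c(seps - 1L, nchar(rest))), decreasing = TRUE)
    first_semantic <- NULL
    for (end in cut_ends) {
      if (end < 1L) next
      candidate <- substr(rest, 1, end)
      res <- tryCatch(
        list(f = parse_variant_suffix_structured(candidate)),
        pombelint_semantic_error = function(e) e,
        pombelint_syntax_error = function(e) NULL
      )
      if (is.null(res)) next
      if (inherits(res, "condition")) {
        if (is.null(first_semantic)) first_semantic <- res
        next
      }
      return(mk(res$f, nchar(candidate)))
    }
    if (!is.null(first_semantic)) stop(first_semantic)
  }

  # short-name fallback for a '-' chunk that is no other kind of element
  if (startsWith(rest, "-")) {
    after <- top_level_positions(rest, c("-", ":"))
    after <- after[after > 1L]
    chunk_end <- if (length(after) > 0) min(after) - 1L else nchar(rest)
    chunk <- substr(rest, 2, chunk_end)
    if (grepl("^[A-Za-z0-9_]+$", chunk) &&
        !token_resolves_as_element(chunk, state)) {
      add_lint(state, new_lint(
        "info", "short_name",
        sprintf("allele short name '%s-%s' (lesion not machine readable)",
                sym, chunk),
        pos, after_sym + chunk_end))
      if (grepl("_", chunk, fixed = TRUE)) {
        add_lint(state, new_lint(
          "error", "underscore_in_name",
          "underscores are not allowed in allele variant short names",
          after_sym + 1L, after_sym + chunk_end,
          suggestion = gsub("_", "-", chunk, fixed = TRUE)))
      }
      return(mk(list(vf_short_name(chunk)), chunk_end))
    }
  }

  # truncation-style names: gene followed directly by Δ plus letters
  tm <- regexpr("^Δ[A-Za-z][A-Za-z0-9]*", rest)
  if (tm == 1L) {
    chunk <- substr(rest, 1, attr(tm, "match.length"))
    add_lint(state, new_lint(
      "warning", "truncation_name",
      sprintf("truncation short name '%s%s' is discouraged", sym, chunk),
      pos, after_sym + attr(tm, "match.length")))
    return(mk(list(vf_short_name(chunk, sep = "")), attr(tm, "match.length")))
  }

  mk(list(), 0L)
}

scan_chain <- function(text, state) {
  if (!nzchar(text)) parse_error("empty allele component")
  comps <- list()
  pos <- 1L
  n <- nchar(text)
  repeat {
    el <- scan_element(text, pos, state)
    comps <- c(comps, list(el$component))
    pos <- el$pos
    if (pos > n) break
    sep <- substr(text, pos, pos)
    if (!sep %in% c("-", ":")) {
      parse_error(sprintf("unexpected character '%s'", sep),
                  start = pos, end = pos)
    }
    pos <- pos + 1L
    if (pos > n) {
      last <- comps[[length(comps)]]
      if (sep == "-" && last$kind == "gene" && length(last$features) == 0) {
        # trailing '-': unknown loss-of-function allele
        comps[[length(comps)]]$features <- list(vf_loss_of_function())
        break
      }
      parse_error("dangling separator at end of allele name",
                  start = pos - 1L, end = pos - 1L)
    }
    comps[[length(comps)]]$link <- sep
  }
  comps
}

chain_gene_components <- function(comps) {
  out <- list()
  for (c in comps) {
    if (c$kind == "gene") out <- c(out, list(c))
    if (c$kind == "group") out <- c(out, chain_gene_components(c$components))
  }
  out
}

chain_has_nonvariant <- function(comps) {
  any(vapply(comps, function(c) {
    c$kind %in% c("feature", "subcomponent", "linker") ||
      (c$kind == "group" && chain_has_nonvariant(c$components))
  }, TRUE))
}

# Alleles -------------------------------------------------------------------

new_allele <- function(left, right = NULL, anchor = NULL, locus_side = NA,
                       locus_kind = NA, endogenous = FALSE,
                       lints = no_lints()) {
  structure(
    list(left = left, right = right, anchor = anchor,
         locus_side = locus_side, locus_kind = locus_kind,
         endogenous = endogenous, lints = lints),
    class = "pomb_allele"
  )
}

single_gene_chain <- function(comps) {
  length(comps) == 1 && comps[[1]]$kind == "gene"
}

#' Parse an allele name
#'
#' @param text one allele token (no spaces).
#' @param lexicon feature lexicon data frame (see [feature_lexicon()]).
#' @param genes character vector of known gene symbols; symbols matching
#'   the classic pattern or a systematic-identifier prefix are recognized
#'   even when not listed, but hyphenated symbols (`ase1-ot1`, `mat1-Mc`)
#'   are only found through this set (the shipped exception lexicon is
#'   always included).
#' @param allow_locus set `FALSE` to reject `::` (inside plasmid element
#'   lists).
#' @return a `pomb_allele`; findings are in `$lints`.
#' @examples
#' parse_allele("ura4Δ::kanMX6")
#' parse_allele("ase1-P114A,Q117A")
#' @export
parse_allele <- function(text, lexicon = feature_lexicon(),
                         genes = character(), allow_locus = TRUE) {
  norm <- normalize_genotype_text(text)
  text <- norm$text
  if (grepl("[[:space:]]", text)) {
    parse_error("allele names cannot contain spaces", "space_in_allele")
  }
  if (!nzchar(text)) parse_error("empty allele name")
  state <- parser_state(lexicon, c(genes, symbol_exceptions()$symbol))

  # optional genomic anchor at the end
  anchor <- NULL
  at <- regexpr("@", text, fixed = TRUE)
  if (at != -1) {
    anchor <- parse_genomic_anchor(substring(text, at))
    text <- substr(text, 1, at - 1L)
  }

  # the insertion locus separator
  dc <- gregexpr("::", text, fixed = TRUE)[[1]]
  if (dc[1] != -1 && length(dc) > 1) {
    parse_error("an allele name may contain at most one '::'",
                "double_insertion_locus")
  }
  if (dc[1] != -1 && !allow_locus) {
    parse_error("'::' is not supported inside a plasmid element list")
  }

  if (dc[1] == -1) {
    left <- scan_chain(text, state)
    genes_in <- chain_gene_components(left)
    if (length(genes_in) > 1) {
      parse_error(
        "a gene fusion or chimera needs an explicit insertion locus ('locus::...')",
        "fusion_requires_locus")
    }
    endo <- length(genes_in) == 1 && chain_has_nonvariant(left)
    return(new_allele(left, anchor = anchor, endogenous = endo,
                      lints = bind_lints(norm$lints, state_lints(state))))
  }

  left_text <- substr(text, 1, dc[1] - 1L)
  right_text <- substring(text, dc[1] + 2L)
  left <- scan_chain(left_text, state)
  right <- scan_chain(right_text, state)

  if (single_gene_chain(left)) {
    locus_kind <- locus_kind_of(left[[1]], anchor)
    if (locus_kind == "ambiguous") {
      add_lint(state, new_lint(
        "warning", "ambiguous_locus",
        sprintf("'%s::' does not say whether the locus allele is wild type; use '%s+::' or '%sΔ::'",
                left[[1]]$symbol, left[[1]]$symbol, left[[1]]$symbol)))
    }
    return(new_allele(left, right, anchor = anchor, locus_side = "left",
                      locus_kind = locus_kind,
                      lints = bind_lints(norm$lints, state_lints(state))))
  }

  # construct::marker form: the construct sits in the locus of its single
  # host gene, and the element after '::' is a marker allele of that locus
  if (single_gene_chain(right) && length(chain_gene_components(left)) >= 1) {
    return(new_allele(left, right, anchor = anchor, locus_side = "right",
                      locus_kind = "marker_right",
                      lints = bind_lints(norm$lints, state_lints(state))))
  }
  parse_error("cannot resolve the insertion locus on either side of '::'")
}

locus_kind_of <- function(gene_comp, anchor) {
  types <- vapply(gene_comp$features, function(f) f$type, "")
  if ("full_deletion" %in% types) return("deletion")
  if ("wild_type" %in% types) return("wildtype")
  if (length(types) == 0) {
    return(if (!is.null(anchor)) "disruption" else "ambiguous")
  }
  "allele"
}

# Genotypes ------------------------------------------------------------------

new_genotype <- function(mating_type = NA_character_, loci = list(),
                         plasmids = list(), lints = no_lints()) {
  structure(list(mating_type = mating_type, loci = loci,
                 plasmids = plasmids, lints = lints),
            class = "pomb_genotype")
}

#' Parse a genotype string
#'
#' @inheritParams parse_allele
#' @param text genotype string (space-separated allele names, optional
#'   mating type, optional `[plasmid ...]` groups). The empty string is
#'   the wild-type genotype.
#' @return a `pomb_genotype`.
#' @examples
#' parse_genotype("h- ura4-D18 [pXYZ]")
#' parse_genotype("ura4+/ura4-294")
#' @export
parse_genotype <- function(text, lexicon = feature_lexicon(),
                           genes = character()) {
  tk <- tokenize_genotype(text)
  lints <- tk$lints
  mating <- NA_character_
  loci <- list()
  plasmids <- list()
  for (i in seq_len(nrow(tk$tokens))) {
    tok <- tk$tokens$text[i]
    if (tk$tokens$type[i] == "plasmid") {
      parts <- strsplit(tok, " ", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) == 0) parse_error("empty plasmid group")
      elements <- lapply(parts[-1], parse_allele, lexicon = lexicon,
                         genes = genes, allow_locus = FALSE)
      for (e in elements) lints <- bind_lints(lints, e$lints)
      plasmids <- c(plasmids, list(list(name = parts[1], elements = elements)))
      next
    }
    if (tok %in% mating_types()) {
      if (!is.na(mating)) {
        lints <- bind_lints(lints, new_lint(
          "warning", "parse_error", "more than one mating-type token"))
      }
      mating <- tok
      next
    }
    halves <- split_top_level(tok, "/")
    if (length(halves$pieces) > 2) {
      parse_error("a diploid locus has exactly two alleles",
                  start = tk$tokens$start[i])
    }
    alleles <- lapply(halves$pieces, parse_allele, lexicon = lexicon,
                      genes = genes)
    for (a in alleles) lints <- bind_lints(lints, a$lints)
    loci <- c(loci, list(list(alleles = alleles,
                              diploid = length(alleles) == 2)))
  }
  new_genotype(mating, loci, plasmids, lints)
}

# Serialization ---------------------------------------------------------------

serialize_component <- function(c) {
  switch(c$kind,
    gene = paste0(
      c$symbol,
      if (!is.na(c$transcript)) paste0(".", c$transcript) else "",
      serialize_variant_features(c$features)),
    subcomponent = paste0(
      if (!is.na(c$provenance)) paste0(c$provenance, "\\") else "",
      c$part, ".", c$host),
    feature = paste0(
      if (!is.na(c$provenance)) paste0(c$provenance, "\\") else "",
      c$token),
    linker = paste0("(", c$residues, ")"),
    group = paste0("(", serialize_chain(c$components), ")"),
    parse_error(sprintf("unknown component kind '%s'", c$kind))
  )
}

serialize_chain <- function(comps) {
  out <- character(0)
  for (i in seq_along(comps)) {
    out <- c(out, serialize_component(comps[[i]]))
    if (i < length(comps)) out <- c(out, comps[[i]]$link)
  }
  paste(out, collapse = "")
}

#' Serialize parsed records back to guideline text
#'
#' Inverses of [parse_allele()] and [parse_genotype()]: parsing the
#' serialized text reproduces the structure, and serializing a parse
#' reproduces the input (modulo recorded character normalizations).
#'
#' @param allele,genotype parsed records.
#' @return a string.
#' @export
serialize_allele <- function(allele) {
  out <- serialize_chain(allele$left)
  if (!is.null(allele$right)) {
    out <- paste0(out, "::", serialize_chain(allele$right))
  }
  if (!is.null(allele$anchor)) out <- paste0(out, serialize_anchor(allele$anchor))
  out
}

#' @rdname serialize_allele
#' @export
serialize_genotype <- function(genotype) {
  parts <- character(0)
  if (!is.na(genotype$mating_type)) parts <- genotype$mating_type
  for (l in genotype$loci) {
    parts <- c(parts, paste(vapply(l$alleles, serialize_allele, ""),
                            collapse = "/"))
  }
  for (p in genotype$plasmids) {
    inner <- paste(c(p$name, vapply(p$elements, serialize_allele, "")),
                   collapse = " ")
    parts <- c(parts, paste0("[", inner, "]"))
  }
  paste(parts, collapse = " ")
}

#' @export
print.pomb_allele <- function(x, ...) {
  cat("<allele>", serialize_allele(x), "\n")
  describe_chain(x$left, indent = "  ")
  if (!is.null(x$right)) {
    cat("  :: (insertion locus side:", x$locus_side, ")\n")
    describe_chain(x$right, indent = "  ")
  }
  if (!is.null(x$anchor)) cat("  anchor:", serialize_anchor(x$anchor), "\n")
  if (nrow(x$lints) > 0) print(x$lints)
  invisible(x)
}

describe_component <- function(c) {
  switch(c$kind,
    gene = sprintf("gene %s%s%s", c$symbol,
                   if (!is.na(c$transcript)) sprintf(" (transcript %d)", c$transcript) else "",
                   if (length(c$features)) paste0(" ", serialize_variant_features(c$features)) else ""),
    subcomponent = sprintf("%s of %s", switch(c$part, P = "promoter",
                                              T = "terminator", c$part), c$host),
    feature = sprintf("%s [%s]%s", c$token, c$category,
                      if (!is.na(c$provenance)) sprintf(" from %s", c$provenance) else ""),
    linker = sprintf("linker %s", c$residues),
    group = sprintf("group (%s)", serialize_chain(c$components))
  )
}

describe_chain <- function(comps, indent = "") {
  for (c in comps) {
    link <- switch(c$link, "-" = " -(functionally linked)-", ":" = " :(adjacent):", "")
    cat(indent, describe_component(c), link, "\n", sep = "")
  }
}

#' @export
print.pomb_genotype <- function(x, ...) {
  cat("<genotype>", serialize_genotype(x), "\n")
  if (!is.na(x$mating_type)) cat("  mating type:", x$mating_type, "\n")
  cat(sprintf("  %d locus entr%s, %d plasmid%s\n", length(x$loci),
              if (length(x$loci) == 1) "y" else "ies",
              length(x$plasmids), if (length(x$plasmids) == 1) "" else "s"))
  if (nrow(x$lints) > 0) print(x$lints)
  invisible(x)
}
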