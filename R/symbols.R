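#' Gene symbols
#'
#' Fission-yeast gene symbols are three lowercase Latin letters followed by
#' one or more digits, with no punctuation (`cdc25`). Noncoding RNA genes
#' that regulate a protein-coding gene reuse the regulated gene's symbol
#' plus a relationship suffix: `-ot<i>` (overlapping transcript, same
#' strand), `-as<i>` (overlapping antisense), `-dt` (divergent transcript,
#' no index), `-it<i>` (intronic). A curated exception lexicon covers the
#' historical symbols that predate these rules, systematic identifiers
#' (`SPAPB1A10.09`, `SPNCRNA.1530`, ...) pass through by prefix pattern,
#' and transcript-qualified forms (`zas1.2`) name a non-primary transcript.
#'
#' @name gene-symbols
NULL

SYMBOL_CLASSIC_RE <- "^[a-z]{3}[0-9]+$"
SYMBOL_NCRNA_RE <- "^([a-z]{3}[0-9]+)-(ot|as|it)([0-9]+)$"
SYMBOL_DT_RE <- "^([a-z]{3}[0-9]+)-dt$"
SYMBOL_TRANSCRIPT_RE <- "^([a-z]{3}[0-9]+)\\.([0-9]+)$"
# Systematic identifiers (locus tags): SP... for S. pombe, SJAG for
# S. japonicus, plus the other sequenced clade members. A digit is
# required somewhere (SPAPB1A10.09, SPNCRNA.1530, SPATRNAALA.01).
SYSTEMATIC_ID_RE <- "^(?=.*[0-9])(SP|SJAG|SOCG|SPOG|SOMG)[A-Za-z0-9]*(\\.[0-9]+c?)?$"

new_gene_symbol <- function(text, kind, base_gene = NA_character_,
                            index = NA_integer_) {
  structure(
    list(text = text, kind = kind, base_gene = base_gene,
         index = as.integer(index)),
    class = "pomb_symbol"
  )
}

#' @export
format.pomb_symbol <- function(x, ...) x$text

#' @export
print.pomb_symbol <- function(x, ...) {
  extra <- if (!is.na(x$base_gene)) {
    sprintf(" (base gene %s%s)", x$base_gene,
            if (!is.na(x$index)) sprintf(", index %d", x$index) else "")
  } else ""
  cat(sprintf("<gene symbol> %s [%s]%s\n", x$text, x$kind, extra))
  invisible(x)
}

#' Validate and classify a gene symbol
#'
#' Classifies `text` as a classic symbol, an ncRNA relationship symbol, a
#' lexicon exception, a systematic identifier, or a transcript-qualified
#' symbol. When no rule matches, returns the findings explaining which
#' rules were violated instead.
#'
#' @param text a single symbol, no whitespace.
#' @param lexicon exception lexicon data frame (see [symbol_exceptions()]).
#' @return a `pomb_symbol` on success, otherwise a `pomb_lints` data frame.
#' @examples
#' validate_gene_symbol("cdc25")
#' validate_gene_symbol("ase1-dt")
#' validate_gene_symbol("Cdc25") # lint: case
#' @export
validate_gene_symbol <- function(text, lexicon = symbol_exceptions()) {
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    parse_error("gene symbol must be a single non-empty string", "parse_error")
  }
  if (grepl("[[:space:]]", text)) {
    parse_error("gene symbol must not contain whitespace", "space_in_allele")
  }
  if (text %in% lexicon$symbol) {
    return(new_gene_symbol(text, "exception"))
  }
  if (grepl(SYMBOL_CLASSIC_RE, text)) {
    return(new_gene_symbol(text, "classic", base_gene = text))
  }
  if (grepl(SYMBOL_NCRNA_RE, text, perl = TRUE) ||
      grepl(SYMBOL_DT_RE, text, perl = TRUE)) {
    return(classify_ncrna_symbol(text))
  }
  m <- regexec(SYMBOL_TRANSCRIPT_RE, text)
  if (m[[1]][1] != -1) {
    g <- regmatches(text, m)[[1]]
    return(new_gene_symbol(text, "transcript_qualified", base_gene = g[2],
                           index = as.integer(g[3])))
  }
  if (grepl(SYSTEMATIC_ID_RE, text, perl = TRUE)) {
    return(new_gene_symbol(text, "systematic_id"))
  }
  lints <- no_lints()
  if (grepl("[A-Z]", text)) {
    lints <- bind_lints(lints, new_lint(
      "error", "symbol_case",
      "uppercase letters are not allowed in gene symbols", 1, nchar(text)
    ))
  }
  if (grepl("[^A-Za-z0-9]", text)) {
    lints <- bind_lints(lints, new_lint(
      "error", "symbol_punctuation",
      "gene symbols must not contain punctuation", 1, nchar(text)
    ))
  }
  if (!grepl("^[a-z]{3}[0-9]+", text)) {
    lints <- bind_lints(lints, new_lint(
      "error", "symbol_pattern",
      "gene symbols are 3 lowercase Latin letters followed by digits",
      1, nchar(text)
    ))
  }
  # Species references cannot be told apart from valid symbols mechanically
  # (spl1 is a legitimate tRNA symbol), so this is a warning, never an error.
  if (grepl("^sp[a-z]*$", text) || grepl("^[a-z]{3}[0-9]+p$", text)) {
    lints <- bind_lints(lints, new_lint(
      "warning", "species_prefix",
      "symbol may embed a species reference ('sp'/'p' forms are discouraged)",
      1, nchar(text)
    ))
  }
  if (nrow(lints) == 0) {
    lints <- new_lint("error", "symbol_pattern",
                      "symbol matches no naming rule or exception",
                      1, nchar(text))
  }
  lints
}

#' Classify an ncRNA relationship symbol
#'
#' Splits on the final `-ot`/`-as`/`-dt`/`-it` suffix. `-dt` carries no
#' index (a gene has a single divergent transcript); `-ot`/`-as`/`-it`
#' carry an index of 1 or more.
#'
#' @param text the symbol; without a relationship suffix it falls through
#'   to the conventional (classic) classification.
#' @return a `pomb_symbol`; if `-dt` is followed by digits, a lint frame.
#' @export
classify_ncrna_symbol <- function(text) {
  m <- regexec(SYMBOL_NCRNA_RE, text, perl = TRUE)
  if (m[[1]][1] != -1) {
    g <- regmatches(text, m)[[1]]
    return(new_gene_symbol(text, paste0("ncrna_", g[3]), base_gene = g[2],
                           index = as.integer(g[4])))
  }
  if (grepl(SYMBOL_DT_RE, text, perl = TRUE)) {
    base <- sub("-dt$", "", text)
    return(new_gene_symbol(text, "ncrna_dt", base_gene = base))
  }
  if (grepl("^[a-z]{3}[0-9]+-dt[0-9]+$", text)) {
    return(new_lint("error", "dt_index",
                    "a divergent-transcript symbol takes no index",
                    1, nchar(text)))
  }
  # no relationship suffix: conventionally named (classic) or unclassifiable
  if (grepl(SYMBOL_CLASSIC_RE, text)) {
    return(new_gene_symbol(text, "classic", base_gene = text))
  }
  new_gene_symbol(text, "unknown")
}

#' Propose the next free ncRNA symbol for a regulated gene
#'
#' @param base_gene the regulated gene, a classic-kind `pomb_symbol` or its
#'   text.
#' @param relation one of `"ot"`, `"as"`, `"dt"`, `"it"`.
#' @param existing character vector of symbols already assigned.
#' @return the proposed symbol text.
#' @examples
#' propose_ncrna_symbol("ase1", "ot", c("ase1-ot1"))
#' @export
propose_ncrna_symbol <- function(base_gene, relation, existing = character()) {
  if (inherits(base_gene, "pomb_symbol")) {
    if (base_gene$kind != "classic") {
      parse_error("ncRNA symbols are derived from classic gene symbols")
    }
    base_gene <- base_gene$text
  }
  if (!grepl(SYMBOL_CLASSIC_RE, base_gene)) {
    parse_error("ncRNA symbols are derived from classic gene symbols")
  }
  relation <- match.arg(relation, c("ot", "as", "dt", "it"))
  if (relation == "dt") {
    sym <- paste0(base_gene, "-dt")
    if (sym %in% existing) {
      parse_error("the divergent-transcript symbol is unique per gene and already exists")
    }
    return(sym)
  }
  idx <- 1L
  repeat {
    sym <- paste0(base_gene, "-", relation, idx)
    if (!(sym %in% existing)) return(sym)
    idx <- idx + 1L
  }
}
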