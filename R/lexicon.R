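#' Configuration lexica
#'
#' The grammar is driven by small editable plain-text tables rather than
#' hard-coded lists: the historical gene-symbol exceptions, the known
#' nonvariant-feature tokens (tags, markers, promoters, recombination
#' sites, encoded tools), and the legacy-token harmonization table. The
#' package ships defaults seeded from the published guidelines; each loader
#' accepts a path to a user-supplied replacement with the same columns.
#'
#' @param path TSV file, or `NULL` for the shipped default. Files are
#'   two-or-more-column UTF-8 TSVs with `#` comment lines.
#' @return a data frame.
#' @name lexica
NULL

read_lexicon_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "pombelint", mustWork = TRUE)
}

.lexicon_cache <- new.env(parent = emptyenv())

cached <- function(key, value) {
  if (!exists(key, envir = .lexicon_cache)) {
    assign(key, force(value), envir = .lexicon_cache)
  }
  get(key, envir = .lexicon_cache)
}

#' @rdname lexica
#' @export
symbol_exceptions <- function(path = NULL) {
  if (!is.null(path)) return(read_lexicon_tsv(path))
  cached("exceptions", read_lexicon_tsv(pkg_extdata("symbol_exceptions.tsv")))
}

#' @rdname lexica
#' @export
feature_lexicon <- function(path = NULL) {
  if (!is.null(path)) return(read_lexicon_tsv(path))
  cached("features", read_lexicon_tsv(pkg_extdata("feature_lexicon.tsv")))
}

#' @rdname lexica
#' @export
harmonization_table <- function(path = NULL) {
  if (!is.null(path)) return(read_lexicon_tsv(path))
  cached("harmonization", read_lexicon_tsv(pkg_extdata("harmonization.tsv")))
}

#' Published variant-suffix regular expressions
#'
#' The pattern set for allele gene-variant-feature suffixes, one row per
#' variant type, kept as a versioned plain-text resource.
#'
#' @return data frame with columns `name` and `pattern` (PCRE).
#' @export
variant_regex_table <- function() {
  cached("variant_regex", read_lexicon_tsv(pkg_extdata("variant_regex.tsv")))
}

#' Mating-type tokens recognized in genotypes
#'
#' `h+` and `h-` are the heterothallic types, `h90` the homothallic
#' switching configuration, and `h?` an unknown mating type.
#' @export
mating_types <- function() c("h+", "h-", "h90", "h?")
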