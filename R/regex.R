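#' Regular-expression recognizer for variant suffixes
#'
#' A single anchored PCRE assembled from the published per-variant-type
#' patterns, restricted to one product alphabet as the pattern file's
#' footnote recommends, and extended with the comma-separated CTD repeat
#' list that the guideline text allows alongside ranges. This recognizer is
#' independent of the structured parser; the two are required to accept
#' and reject identically (over surface syntax) and that agreement is
#' exercised as a property test.
#'
#' @param product_kind `"protein"` or `"rna"`.
#' @return a single PCRE string (use with `perl = TRUE`).
#' @export
variant_suffix_regex <- function(product_kind = "protein") {
  letters_cls <- product_alphabet(product_kind)
  res <- sprintf("[%s]", letters_cls)      # one residue
  res_star <- sprintf("[%s*]", letters_cls)

  ranges <- "\\(((?<!\\d)\\d+-\\d+,?)+(?<!,)\\)"
  ret <- ranges
  del <- paste0("Δ", ranges)
  edit1 <- paste0(res, "+\\d+", res_star, "+")
  edits <- paste0("-((?<=[,-])", edit1, ",?)+(?<!,)")
  sel1 <- "r\\d+(-r\\d+(-\\d+)?)?"
  sel <- paste0("\\(", sel1, "(,", sel1, ")*\\)")
  ctd_item <- paste0("(", del, "|", edit1, "|Δ)")
  ctd <- paste0("-CTD-((?<=[,-])", ctd_item, "(", sel, ")?,?)+(?<!,)")

  body <- paste0(
    "(?:(?:", del, "|", ret, ")(?:", edits, ")?(?:", ctd, ")?",
    "|", edits, "(?:", ctd, ")?",
    "|", ctd, ")"
  )
  paste0("^(?:\\+|Δ|", body, ")$")
}

#' Match a suffix against the assembled recognizer
#'
#' @param text suffix text (vectorized).
#' @inheritParams variant_suffix_regex
#' @return logical vector.
#' @export
variant_suffix_matches <- function(text, product_kind = "protein") {
  grepl(variant_suffix_regex(product_kind), text, perl = TRUE)
}
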