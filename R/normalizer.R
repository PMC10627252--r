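#' Canonicalization and synonym detection
#'
#' The same allele can be written several guideline-accepted ways: a
#' partial deletion as retained or removed residues, a tagged gene with
#' or without its implied endogenous locus, a flanking-marker construct
#' with either flanking allele leading the name, and legacy component
#' spellings (`P3Xnmt1`, `kanr`). Canonicalization rewrites a parsed
#' allele into one preferred surface form so that synonymous names
#' compare equal:
#'
#' * legacy tokens are harmonized (`P3Xnmt1` -> `P3nmt1`, `kanr` ->
#'   `kanMX6`); underscores in short names become hyphens;
#' * retained-mode partial deletions become removed-mode (`Δ`) when the
#'   reference length is known;
#' * an allele with a single host gene and nonvariant features is
#'   materialized at its endogenous locus (`mCherry-atb2:kanMX6` ->
#'   `atb2Δ::mCherry-atb2:kanMX6`);
#' * when a construct carries an allele of its insertion locus at either
#'   flank, the flanking allele whose text sorts first leads the name.
#'
#' @name canonicalization
NULL

#' Harmonize one legacy component token
#'
#' Maps known aliases onto the recommended token (anchored match against
#' the harmonization table), rewrites underscores in short names to
#' hyphens, and recognizes — without renaming — legacy period-separated
#' short names. Idempotent: harmonizing a harmonized token is a no-op.
#'
#' @param token component token text.
#' @param table harmonization table (see [harmonization_table()]).
#' @return the recommended token, with attributes `note` (provenance
#'   message or `NULL`) and `changed`.
#' @examples
#' harmonize_token("P3Xnmt1")
#' harmonize_token("kanr")
#' harmonize_token("ase1_x1")
#' @export
harmonize_token <- function(token, table = harmonization_table()) {
  for (i in seq_len(nrow(table))) {
    if (grepl(paste0("^(", table$legacy_pattern[i], ")$"), token)) {
      out <- table$recommended[i]
      if (identical(out, token)) break
      return(structure(out, changed = TRUE,
                       note = sprintf("legacy %s name '%s' harmonized to '%s'",
                                      table$category[i], token, out)))
    }
  }
  if (grepl("_", token, fixed = TRUE)) {
    out <- gsub("_", "-", token, fixed = TRUE)
    return(structure(out, changed = TRUE,
                     note = sprintf("underscores changed to hyphens in '%s' (original retained as synonym)",
                                    token)))
  }
  if (grepl("^[a-z]{3}[0-9]+\\.[A-Za-z][A-Za-z0-9]*$", token)) {
    return(structure(token, changed = FALSE,
                     note = sprintf("legacy period separator in '%s'; existing alleles are not renamed",
                                    token)))
  }
  structure(token, changed = FALSE, note = NULL)
}

# component-level canonicalization ------------------------------------------

canonicalize_component <- function(comp, refdb, table, lexicon) {
  if (comp$kind == "group") {
    comp$components <- lapply(comp$components, canonicalize_component,
                              refdb = refdb, table = table, lexicon = lexicon)
    return(comp)
  }
  if (comp$kind == "feature") {
    h <- harmonize_token(comp$token, table)
    if (isTRUE(attr(h, "changed"))) {
      comp$token <- as.character(h)
      cat_new <- feature_category(comp$token,
                                  list(lexicon = lexicon, genes = character()))
      if (!is.na(cat_new)) comp$category <- cat_new
    }
    return(comp)
  }
  if (comp$kind != "gene") return(comp)
  gene <- if (!is.null(refdb) && comp$symbol %in% names(refdb)) {
    refdb[[comp$symbol]]
  } else NULL
  comp$features <- lapply(comp$features, function(f) {
    if (f$type == "partial_deletion" && f$mode == "retained") {
      if (!is.null(gene)) {
        tr <- if (is.na(comp$transcript)) 1L else comp$transcript
        L <- named_length(gene, tr)
        if (max(f$ranges[, 2]) <= L) {
          return(vf_partial_deletion("removed", complement_ranges(f$ranges, L)))
        }
      }
      return(f)  # no usable reference length: left in retained mode
    }
    if (f$type == "short_name" && f$sep == "_") {
      return(vf_short_name(gsub("_", "-", f$text, fixed = TRUE), sep = "-"))
    }
    if (f$type == "short_name" && grepl("_", f$text, fixed = TRUE)) {
      return(vf_short_name(gsub("_", "-", f$text, fixed = TRUE), sep = f$sep))
    }
    f
  })
  comp
}

# string sort in a fixed (C-locale) order, independent of the session locale
c_sort_first <- function(a, b) {
  sort(c(a, b), method = "radix")[1]
}

flanking_swap <- function(allele) {
  # applicable when the leading locus allele's gene reappears as the final
  # adjacent component of the construct (pJK210-style flanking integration)
  if (is.null(allele$right) || !identical(allele$locus_side, "left")) return(NULL)
  if (!single_gene_chain(allele$left)) return(NULL)
  locus_sym <- allele$left[[1]]$symbol
  n <- length(allele$right)
  if (n < 2) return(NULL)
  last <- allele$right[[n]]
  if (last$kind != "gene" || last$symbol != locus_sym) return(NULL)
  if (allele$right[[n - 1]]$link != ":") return(NULL)
  # deletion loci do not flank anything: the ORF is gone
  if (allele$locus_kind %in% c("deletion", "disruption")) return(NULL)
  swapped <- allele
  new_lead <- last
  new_lead$link <- ""
  old_lead <- allele$left[[1]]
  old_lead$link <- ""
  swapped$left <- list(new_lead)
  swapped$right <- c(allele$right[-n], list(old_lead))
  swapped$locus_kind <- locus_kind_of(new_lead, allele$anchor)
  swapped
}

#' List the accepted flanking-locus serializations of an allele
#'
#' For a construct carrying an allele of its insertion locus at either
#' flank, both orders — either flanking allele leading the name — are
#' accepted and synonymous. Returns all accepted serializations (one
#' element when the flanking rule does not apply).
#'
#' @param allele a `pomb_allele` or allele text.
#' @inheritParams canonicalize_allele
#' @return character vector of accepted, pairwise-synonymous names.
#' @export
enumerate_flanking_forms <- function(allele, lexicon = feature_lexicon(),
                                     genes = character()) {
  if (is.character(allele)) {
    allele <- parse_allele(allele, lexicon = lexicon, genes = genes)
  }
  swapped <- flanking_swap(allele)
  if (is.null(swapped)) return(serialize_allele(allele))
  unique(c(serialize_allele(allele), serialize_allele(swapped)))
}

#' Canonicalize a parsed allele
#'
#' @param allele a `pomb_allele` (or allele text, which is parsed first).
#' @param refdb optional reference set, needed to convert retained-mode
#'   partial deletions (left untouched, with a note, when absent).
#' @param lexicon feature lexicon.
#' @param genes known gene symbols.
#' @param table harmonization table.
#' @return the canonical `pomb_allele`. Idempotent:
#'   `canonicalize_allele(canonicalize_allele(x))` equals
#'   `canonicalize_allele(x)`.
#' @examples
#' db <- NULL
#' serialize_allele(canonicalize_allele("mCherry-atb2:kanMX6"))
#' @export
canonicalize_allele <- function(allele, refdb = NULL,
                                lexicon = feature_lexicon(),
                                genes = character(),
                                table = harmonization_table()) {
  if (is.character(allele)) {
    allele <- parse_allele(allele, lexicon = lexicon,
                           genes = union(genes, names(refdb)))
  }
  allele$left <- lapply(allele$left, canonicalize_component, refdb = refdb,
                        table = table, lexicon = lexicon)
  if (!is.null(allele$right)) {
    allele$right <- lapply(allele$right, canonicalize_component,
                           refdb = refdb, table = table, lexicon = lexicon)
  }

  # materialize the implied endogenous locus of a single-host-gene construct
  if (is.null(allele$right) && isTRUE(allele$endogenous)) {
    gene_comp <- chain_gene_components(allele$left)[[1]]
    locus <- new_component("gene", symbol = gene_comp$symbol,
                           transcript = NA_integer_,
                           features = list(vf_full_deletion()))
    allele$right <- allele$left
    allele$left <- list(locus)
    allele$locus_side <- "left"
    allele$locus_kind <- "deletion"
    allele$endogenous <- FALSE
  }

  # fixed orientation for flanking-locus synonym pairs
  swapped <- flanking_swap(allele)
  if (!is.null(swapped)) {
    mine <- serialize_chain(allele$left)
    theirs <- serialize_chain(swapped$left)
    if (!identical(c_sort_first(mine, theirs), mine)) allele <- swapped
  }
  allele
}

#' Are two allele names synonymous?
#'
#' True when the canonical forms are structurally identical. Reflexive,
#' symmetric and transitive. Deletion alleles built with different
#' constructions (`ura4Δ` vs `ura4Δ::kanMX6`) are not synonymous: the
#' marker is part of the locus structure.
#'
#' @param a,b `pomb_allele` records or allele texts.
#' @inheritParams canonicalize_allele
#' @return logical.
#' @examples
#' are_synonymous("ura4+::P.ase1-ase1-GFP:ura4-294",
#'                "ura4-294::P.ase1-ase1-GFP:ura4+")
#' @export
are_synonymous <- function(a, b, refdb = NULL, lexicon = feature_lexicon(),
                           genes = character()) {
  ca <- canonicalize_allele(a, refdb = refdb, lexicon = lexicon, genes = genes)
  cb <- canonicalize_allele(b, refdb = refdb, lexicon = lexicon, genes = genes)
  identical(serialize_allele(ca), serialize_allele(cb))
}
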