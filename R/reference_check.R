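#' Reference gene sets and sequence-aware allele validation
#'
#' The central error class genotype nomenclature exists to catch is an
#' allele referring to residues not present at the indicated position.
#' A reference gene set supplies, per gene, the product sequence of each
#' transcript (index 1 = primary), the product kind (protein or RNA), a
#' histone flag (histone positions are numbered after removal of the
#' initiator methionine, so named position k is sequence position k+1),
#' and an optional CTD annotation (repeat unit sequence, repeat count,
#' and the protein coordinate where the repeat region starts).
#'
#' The on-disk form is a FASTA of product sequences (record id
#' `<systematic_id>.<transcript>`) plus a metadata TSV with columns
#' `symbol`, `systematic_id`, `product_kind`, `histone`, `ctd_unit`,
#' `ctd_n_repeats`, `ctd_region_start`.
#'
#' @name reference-set
NULL

#' Construct reference gene records in code
#'
#' @param symbol gene symbol.
#' @param systematic_id systematic identifier (locus tag).
#' @param product_kind `"protein"` or `"rna"`.
#' @param transcripts character vector of product sequences, primary first.
#' @param histone apply histone numbering (named position k = sequence
#'   position k + 1).
#' @param ctd optional list `unit`, `n_repeats`, `region_start`.
#' @return a `pomb_ref_gene`.
#' @export
new_ref_gene <- function(symbol, systematic_id, product_kind, transcripts,
                         histone = FALSE, ctd = NULL) {
  stopifnot(product_kind %in% c("protein", "rna"), length(transcripts) >= 1)
  if (histone && product_kind != "protein") {
    parse_error("histone numbering applies to proteins only")
  }
  structure(
    list(symbol = symbol, systematic_id = systematic_id,
         product_kind = product_kind,
         transcripts = as.character(transcripts),
         histone = isTRUE(histone), ctd = ctd),
    class = "pomb_ref_gene"
  )
}

#' @export
print.pomb_ref_gene <- function(x, ...) {
  cat(sprintf("<ref gene> %s (%s), %s, %d transcript(s), length %s%s%s\n",
              x$symbol, x$systematic_id, x$product_kind,
              length(x$transcripts),
              paste(nchar(x$transcripts), collapse = "/"),
              if (x$histone) ", histone numbering" else "",
              if (!is.null(x$ctd)) {
                sprintf(", CTD %s x%d", x$ctd$unit, x$ctd$n_repeats)
              } else ""))
  invisible(x)
}

#' @rdname new_ref_gene
#' @param genes list of `pomb_ref_gene` records.
#' @export
new_refdb <- function(genes) {
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  structure(genes, class = "pomb_refdb")
}

#' @export
print.pomb_refdb <- function(x, ...) {
  cat(sprintf("<reference gene set> %d genes\n", length(x)))
  for (g in x) print(g)
  invisible(x)
}

#' Write / read a reference gene set
#'
#' @param refdb a reference set (from [build_reference_db()] or
#'   [read_reference_db()]).
#' @param fasta,metadata file paths.
#' @return `read_reference_db` returns a `pomb_refdb`;
#'   `write_reference_db` returns the paths invisibly.
#' @export
write_reference_db <- function(refdb, fasta, metadata) {
  seqs <- character(0)
  for (g in refdb) {
    ids <- sprintf("%s.%d", g$systematic_id, seq_along(g$transcripts))
    v <- g$transcripts
    names(v) <- ids
    seqs <- c(seqs, v)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fasta, width = 60)
  meta <- do.call(rbind, lapply(unclass(refdb), function(g) {
    data.frame(symbol = g$symbol, systematic_id = g$systematic_id,
               product_kind = g$product_kind, histone = g$histone,
               ctd_unit = if (is.null(g$ctd)) "" else g$ctd$unit,
               ctd_n_repeats = if (is.null(g$ctd)) NA_integer_ else g$ctd$n_repeats,
               ctd_region_start = if (is.null(g$ctd)) NA_integer_ else
                 (g$ctd$region_start %||% NA_integer_),
               stringsAsFactors = FALSE)
  }))
  write.table(meta, metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, metadata = metadata))
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(fasta, metadata) {
  seqs <- Biostrings::readBStringSet(fasta)
  seq_ids <- names(seqs)
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  genes <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$systematic_id[i]
    mine <- grepl(paste0("^", sid, "\\.[0-9]+$"), seq_ids)
    ids <- seq_ids[mine]
    idx <- as.integer(sub("^.*\\.", "", ids))
    transcripts <- as.character(seqs[mine])[order(idx)]
    ctd <- NULL
    if (!is.na(meta$ctd_unit[i]) && nzchar(meta$ctd_unit[i])) {
      ctd <- list(unit = meta$ctd_unit[i],
                  n_repeats = as.integer(meta$ctd_n_repeats[i]),
                  region_start =
                    if (is.na(meta$ctd_region_start[i])) NULL
                    else as.integer(meta$ctd_region_start[i]))
    }
    new_ref_gene(meta$symbol[i], sid, meta$product_kind[i], transcripts,
                 histone = isTRUE(meta$histone[i] %in% c(TRUE, "TRUE", "true", 1)),
                 ctd = ctd)
  })
  new_refdb(genes)
}

#' Look up a reference residue by named position
#'
#' Applies the histone numbering convention: for histone genes, named
#' position `k` refers to sequence position `k + 1` (numbering starts
#' after the removed initiator methionine).
#'
#' @param gene a `pomb_ref_gene`.
#' @param transcript_index transcript number (1 = primary).
#' @param position 1-based named residue position.
#' @return single residue character.
#' @export
resolve_reference_residue <- function(gene, transcript_index = 1L, position) {
  if (transcript_index < 1L || transcript_index > length(gene$transcripts)) {
    parse_error(sprintf("transcript %d not in reference for %s",
                        transcript_index, gene$symbol),
                "out_of_range", semantic = TRUE)
  }
  seq <- gene$transcripts[[transcript_index]]
  offset <- if (gene$histone) 1L else 0L
  p <- as.integer(position) + offset
  if (position < 1L || p > nchar(seq)) {
    parse_error(sprintf("position %d is outside %s (%d named residues)",
                        position, gene$symbol, nchar(seq) - offset),
                "out_of_range", semantic = TRUE)
  }
  substr(seq, p, p)
}

named_length <- function(gene, transcript_index = 1L) {
  nchar(gene$transcripts[[transcript_index]]) - if (gene$histone) 1L else 0L
}

# lint helpers for reference comparisons ------------------------------------

ref_lint <- function(code, message) new_lint("error", code, message)

check_edit_against <- function(edit, gene, transcript_index, where = "") {
  lints <- no_lints()
  letters_rep <- chars(edit$replaced)
  for (i in seq_along(letters_rep)) {
    p <- edit$position + i - 1L
    res <- tryCatch(resolve_reference_residue(gene, transcript_index, p),
                    pombelint_parse_error = function(e) e)
    if (is_parse_error(res)) {
      lints <- bind_lints(lints, ref_lint(
        "out_of_range",
        sprintf("%s%s: %s", gene$symbol, where, conditionMessage(res))))
    } else if (res != letters_rep[i]) {
      lints <- bind_lints(lints, ref_lint(
        "residue_mismatch",
        sprintf("%s%s: reference mismatch %s≠%s@%d",
                gene$symbol, where, letters_rep[i], res, p)))
    }
  }
  lints
}

check_ranges_against <- function(ranges, gene, transcript_index) {
  L <- named_length(gene, transcript_index)
  if (any(ranges[, 2] > L)) {
    return(ref_lint("out_of_range",
                    sprintf("%s: range end %d exceeds product length %d",
                            gene$symbol, max(ranges[, 2]), L)))
  }
  no_lints()
}

check_ctd_items <- function(items, gene) {
  lints <- no_lints()
  if (is.null(gene$ctd)) {
    return(new_lint("warning", "unknown_gene",
                    sprintf("%s has no CTD annotation in the reference set",
                            gene$symbol)))
  }
  unit <- gene$ctd$unit
  n_rep <- gene$ctd$n_repeats
  for (item in items) {
    reps <- tryCatch(expand_ctd_selectors(item$selectors, n_rep),
                     pombelint_parse_error = function(e) e)
    if (is_parse_error(reps)) {
      lints <- bind_lints(lints, ref_lint(
        "bad_repeat_index",
        sprintf("%s: %s", gene$symbol, conditionMessage(reps))))
    }
    if (item$op == "edit") {
      e <- item$edit
      span_end <- e$position + nchar(e$replaced) - 1L
      if (span_end > nchar(unit)) {
        lints <- bind_lints(lints, ref_lint(
          "out_of_range",
          sprintf("%s: CTD position %d exceeds the %d-residue repeat unit",
                  gene$symbol, span_end, nchar(unit))))
      } else {
        want <- substr(unit, e$position, span_end)
        if (want != e$replaced) {
          lints <- bind_lints(lints, ref_lint(
            "residue_mismatch",
            sprintf("%s: CTD repeat unit is %s; %s≠%s@%d",
                    gene$symbol, unit, e$replaced, want, e$position)))
        }
      }
    }
    if (item$op == "partial_deletion" && any(item$ranges[, 2] > nchar(unit))) {
      lints <- bind_lints(lints, ref_lint(
        "out_of_range",
        sprintf("%s: CTD deletion range exceeds the %d-residue repeat unit",
                gene$symbol, nchar(unit))))
    }
  }
  lints
}

check_gene_component <- function(comp, refdb) {
  lints <- no_lints()
  gene <- if (comp$symbol %in% names(refdb)) refdb[[comp$symbol]] else NULL
  if (is.null(gene)) {
    if (length(refdb) > 0) {
      lints <- bind_lints(lints, new_lint(
        "warning", "unknown_gene",
        sprintf("gene symbol '%s' is not in the reference set", comp$symbol)))
    }
    return(lints)
  }
  tr <- if (is.na(comp$transcript)) 1L else comp$transcript
  if (tr > length(gene$transcripts)) {
    return(bind_lints(lints, ref_lint(
      "out_of_range",
      sprintf("%s has no transcript %d in the reference set",
              comp$symbol, tr))))
  }
  for (f in comp$features) {
    lints <- bind_lints(lints, switch(f$type,
      partial_deletion = check_ranges_against(f$ranges, gene, tr),
      edits = {
        l <- no_lints()
        for (e in f$edits) {
          if (gene$product_kind == "rna" &&
              grepl("[^ACGT]", paste0(e$replaced, sub("\\*$", "", e$replacement)))) {
            l <- bind_lints(l, ref_lint(
              "rna_letters",
              sprintf("%s is an RNA gene: variants use DNA letters (T instead of U)",
                      gene$symbol)))
          }
          l <- bind_lints(l, check_edit_against(e, gene, tr))
        }
        l
      },
      ctd = check_ctd_items(f$items, gene),
      short_name = {
        l <- no_lints()
        if (grepl("_", f$text, fixed = TRUE)) {
          l <- bind_lints(l, ref_lint(
            "underscore_in_name",
            "underscores are not allowed in allele variant short names"))
        }
        if (f$sep == "" && grepl("^Δ?(N|C)", f$text)) {
          l <- bind_lints(l, new_lint(
            "warning", "truncation_name",
            sprintf("truncation short name '%s%s' is discouraged",
                    comp$symbol, f$text)))
        }
        l
      },
      no_lints()
    ))
  }
  lints
}

#' Validate a parsed allele against a reference gene set
#'
#' Compares every replaced residue of every edit with the reference
#' sequence, bounds-checks deletion ranges and CTD repeat indices, checks
#' the within-repeat wild-type residue of CTD edits against the repeat
#' unit, enforces the DNA-letter convention for RNA genes, and flags
#' unknown gene symbols, underscores in short names and truncation-style
#' names. All findings are lints; nothing stops.
#'
#' @param allele a `pomb_allele`.
#' @param refdb a `pomb_refdb`.
#' @return a `pomb_lints` data frame.
#' @examples
#' db <- build_reference_db(generator_config(seed = 1))
#' a <- parse_allele(paste0(names(db)[1], "Δ"))
#' check_allele(a, db)
#' @export
check_allele <- function(allele, refdb) {
  lints <- no_lints()
  for (comp in c(chain_gene_components(allele$left),
                 chain_gene_components(allele$right %||% list()))) {
    lints <- bind_lints(lints, check_gene_component(comp, refdb))
  }
  lints
}

check_genotype <- function(genotype, refdb) {
  lints <- no_lints()
  for (l in genotype$loci) {
    for (a in l$alleles) lints <- bind_lints(lints, check_allele(a, refdb))
  }
  for (p in genotype$plasmids) {
    for (a in p$elements) lints <- bind_lints(lints, check_allele(a, refdb))
  }
  lints
}

#' Lint a strain list
#'
#' Parses and validates every genotype in a strain list and aggregates
#' the findings per row and per rule code.
#'
#' @param rows a data frame, or the path of a TSV file with one genotype
#'   per row.
#' @param refdb reference gene set, or `NULL` to skip sequence checks.
#' @param lexicon feature lexicon.
#' @param genes known gene symbols (reference symbols are added
#'   automatically).
#' @param column name of the genotype column (defaults to a column named
#'   `genotype`, else the first column).
#' @return a `pomb_report`: per-row findings, counts by code, and an
#'   overall `status` (`"error"`/`"warning"`/`"clean"`).
#' @export
lint_strain_list <- function(rows, refdb = NULL, lexicon = feature_lexicon(),
                             genes = character(), column = NULL) {
  if (is.character(rows)) {
    rows <- read.delim(rows, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                       comment.char = "#")
  }
  if (nrow(rows) > 0 && is.null(column)) {
    column <- if ("genotype" %in% names(rows)) "genotype" else names(rows)[1]
  }
  if (!is.null(refdb)) genes <- union(genes, names(refdb))
  all <- list()
  for (i in seq_len(nrow(rows))) {
    text <- rows[[column]][i]
    found <- tryCatch({
      g <- parse_genotype(text, lexicon = lexicon, genes = genes)
      l <- g$lints
      if (!is.null(refdb)) l <- bind_lints(l, check_genotype(g, refdb))
      l
    }, pombelint_parse_error = function(e) {
      new_lint("error", e$code %||% "parse_error", conditionMessage(e),
               e$start, e$end)
    })
    found <- unique(found)
    if (nrow(found) > 0) {
      found$row <- i
      found$genotype <- text
      all[[length(all) + 1L]] <- found
    }
  }
  lints <- if (length(all)) {
    structure(do.call(rbind, c(all, make.row.names = FALSE)),
              class = c("pomb_lints", "data.frame"))
  } else {
    cbind(no_lints(), data.frame(row = integer(), genotype = character()))
  }
  counts <- if (nrow(lints)) table(lints$code) else table(character())
  status <- if (any(lints$severity == "error")) "error"
            else if (any(lints$severity == "warning")) "warning"
            else "clean"
  structure(list(n_rows = nrow(rows), lints = lints,
                 counts = counts, status = status),
            class = "pomb_report")
}

#' @export
print.pomb_report <- function(x, ...) {
  cat(sprintf("strain list: %d rows, %d findings (%s)\n",
              x$n_rows, nrow(x$lints), x$status))
  if (nrow(x$lints) > 0) {
    tab <- as.data.frame(x$counts)
    names(tab) <- c("code", "n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-24s %d\n", tab$code[i], tab$n[i]))
    }
    for (i in seq_len(nrow(x$lints))) {
      cat(sprintf("row %d [%s] %s: %s\n", x$lints$row[i], x$lints$severity[i],
                  x$lints$code[i], x$lints$message[i]))
    }
  }
  invisible(x)
}

report_json <- function(report) {
  jsonlite::toJSON(list(
    n_rows = report$n_rows,
    status = report$status,
    counts = as.list(report$counts),
    findings = report$lints
  ), auto_unbox = TRUE, dataframe = "rows", na = "null")
}
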