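#' Synthetic reference sets, genotypes and seeded defects
#'
#' Everything the validators need is generated locally: a toy reference
#' gene set (random product sequences with one histone-numbered gene, one
#' CTD tandem-repeat gene and one RNA gene), grammar-valid allele and
#' genotype strings with known ground truth, and controlled single-defect
#' corpora for recall/precision measurement. Each artifact draws from its
#' own pseudo-random stream keyed by `(seed, artifact name)`, so adding a
#' generator does not shift the output of the others, and identical seeds
#' give identical bytes.
#'
#' @name fixtures
NULL

#' Generator configuration
#'
#' @param seed integer master seed.
#' @param n_genes number of reference genes (at least 4: the set always
#'   contains one histone-numbered, one CTD and one RNA gene).
#' @param protein_length_range inclusive bounds for product length
#'   (residues).
#' @param feature_mix named non-negative weights over allele kinds drawn
#'   when generating strain lists.
#' @param defect_rate fraction of strain-list rows carrying one seeded
#'   defect.
#' @param n_rows strain-list length.
#' @param lexicon feature lexicon used for tags/markers/promoters.
#' @return a `pomb_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 12L,
                             protein_length_range = c(200L, 800L),
                             feature_mix = c(wild_type = 1, deletion = 2,
                                             partial_deletion = 2, edits = 4,
                                             ctd = 1, tags = 3, markers = 2,
                                             promoters = 1, plasmid = 1,
                                             diploid = 1),
                             defect_rate = 0,
                             n_rows = 50L,
                             lexicon = feature_lexicon()) {
  stopifnot(n_genes >= 4, all(feature_mix >= 0), sum(feature_mix) > 0,
            defect_rate >= 0, defect_rate <= 1,
            protein_length_range[1] >= 30)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 protein_length_range = as.integer(protein_length_range),
                 feature_mix = feature_mix, defect_rate = defect_rate,
                 n_rows = as.integer(n_rows), lexicon = lexicon),
            class = "pomb_generator_config")
}

# one stream per (seed, artifact): a small string hash folded into the seed
artifact_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_artifact_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(artifact_seed(seed, name))
  force(expr)
}

random_aa <- function(n) {
  paste(sample(chars(AA_LETTERS), n, replace = TRUE), collapse = "")
}

random_symbol <- function(existing) {
  repeat {
    s <- paste0(paste(sample(letters, 3, replace = TRUE), collapse = ""),
                sample(1:99, 1))
    if (!(s %in% existing)) return(s)
  }
}

CTD_UNIT <- "YSPTSPS"
CTD_N_REPEATS <- 29L

#' Build a synthetic reference gene set
#'
#' Deterministic under the config seed. The set always contains one
#' histone-flagged gene, one CTD gene whose sequence carries the stated
#' number of tandem repeat-unit copies at a recorded offset, one RNA gene
#' (DNA-letter sequence), and one gene with a second transcript.
#'
#' @param config a [generator_config()].
#' @return a `pomb_refdb`.
#' @export
build_reference_db <- function(config) {
  with_artifact_seed(config$seed, "refdb", {
    lens <- sample(seq(config$protein_length_range[1],
                       config$protein_length_range[2]), config$n_genes,
                   replace = TRUE)
    syms <- character(0)
    for (i in seq_len(config$n_genes)) syms <- c(syms, random_symbol(syms))
    genes <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      sid <- sprintf("SPSYN%03d", i)
      if (i == 2) {
        # histone-style numbering: positions named after Met removal
        seqs <- paste0("M", random_aa(lens[i] - 1L))
        genes[[i]] <- new_ref_gene(syms[i], sid, "protein", seqs,
                                   histone = TRUE)
      } else if (i == 3) {
        # CTD gene: amino-terminal region then tandem repeats
        prefix <- paste0("M", random_aa(max(lens[i] - 1L, 100L)))
        seqs <- paste0(prefix, strrep(CTD_UNIT, CTD_N_REPEATS))
        genes[[i]] <- new_ref_gene(
          syms[i], sid, "protein", seqs,
          ctd = list(unit = CTD_UNIT, n_repeats = CTD_N_REPEATS,
                     region_start = nchar(prefix) + 1L))
      } else if (i == 4) {
        # RNA gene: transcript-level coordinates, DNA letters
        seqs <- paste(sample(chars(DNA_LETTERS), lens[i], replace = TRUE),
                      collapse = "")
        genes[[i]] <- new_ref_gene(syms[i], sid, "rna", seqs)
      } else if (i == 5) {
        seqs <- c(paste0("M", random_aa(lens[i] - 1L)),
                  paste0("M", random_aa(max(lens[i] - 40L, 30L))))
        genes[[i]] <- new_ref_gene(syms[i], sid, "protein", seqs)
      } else {
        seqs <- paste0("M", random_aa(lens[i] - 1L))
        genes[[i]] <- new_ref_gene(syms[i], sid, "protein", seqs)
      }
    }
    new_refdb(genes)
  })
}

DEFECT_CLASSES <- c("residue_mismatch", "out_of_range", "bad_repeat_index",
                    "underscore_in_name", "forbidden_char",
                    "missing_locus_for_chimera", "space_in_allele")

pick <- function(x, n = 1) x[sample.int(length(x), n)]

lexicon_tokens <- function(lexicon, category) {
  lexicon$token[lexicon$category == category]
}

clean_edit_text <- function(gene, k = NULL) {
  L <- named_length(gene)
  k <- k %||% sample(1:3, 1)
  positions <- sort(sample(seq(2L, L - 1L), k))
  alphabet <- chars(product_alphabet(gene$product_kind))
  edits <- vapply(positions, function(p) {
    ref <- resolve_reference_residue(gene, 1L, p)
    sprintf("%s%d%s", ref, p, pick(setdiff(alphabet, ref)))
  }, "")
  paste0("-", paste(edits, collapse = ","))
}

clean_partial_deletion_text <- function(gene) {
  L <- named_length(gene)
  a <- pick(seq(2L, L - 10L))
  b <- pick(seq(a, min(a + 80L, L)))
  sprintf("Δ(%d-%d)", a, b)
}

clean_ctd_text <- function(gene) {
  unit <- gene$ctd$unit
  p <- sample(nchar(unit), 1)
  ref <- substr(unit, p, p)
  alt <- pick(setdiff(chars(AA_LETTERS), ref))
  sel <- if (runif(1) < 0.5) "" else {
    a <- pick(seq_len(gene$ctd$n_repeats - 1L))
    b <- pick(seq(a + 1L, gene$ctd$n_repeats))
    sprintf("(r%d-r%d)", a, b)
  }
  sprintf("-CTD-%s%d%s%s", ref, p, alt, sel)
}

#' Generate one allele for a reference gene
#'
#' In clean mode the allele is constructed from the reference sequence,
#' so [check_allele()] finds nothing; in defect mode exactly one labelled
#' defect is injected.
#'
#' @param gene a `pomb_ref_gene` from the reference set.
#' @param config a [generator_config()].
#' @param defect `NULL`, or one of `residue_mismatch`, `out_of_range`,
#'   `bad_repeat_index`, `underscore_in_name`, `forbidden_char`,
#'   `missing_locus_for_chimera`, `space_in_allele`.
#' @param refdb the full reference set (needed for the chimera defect).
#' @return list with `text`, `defect` (class or `NA`), and `gene`.
#' @export
generate_allele <- function(gene, config, defect = NULL, refdb = NULL) {
  L <- named_length(gene)
  text <- if (is.null(defect)) {
    kind <- pick(c("wild_type", "deletion", "partial_deletion", "edits",
                   "tags", "markers"))
    switch(kind,
      wild_type = paste0(gene$symbol, "+"),
      deletion = paste0(gene$symbol, "Δ"),
      partial_deletion = paste0(gene$symbol, clean_partial_deletion_text(gene)),
      edits = paste0(gene$symbol, clean_edit_text(gene)),
      tags = paste0(gene$symbol, "-",
                    pick(lexicon_tokens(config$lexicon, "tag"))),
      markers = paste0(gene$symbol, "Δ::",
                       pick(lexicon_tokens(config$lexicon, "marker")))
    )
  } else {
    defect <- match.arg(defect, DEFECT_CLASSES)
    switch(defect,
      residue_mismatch = {
        p <- sample(seq(2L, L - 1L), 1)
        ref <- resolve_reference_residue(gene, 1L, p)
        alphabet <- chars(product_alphabet(gene$product_kind))
        wrong <- pick(setdiff(alphabet, ref))
        sprintf("%s-%s%d%s", gene$symbol, wrong, p,
                pick(setdiff(alphabet, wrong)))
      },
      out_of_range = {
        alphabet <- chars(product_alphabet(gene$product_kind))
        sprintf("%s-%s%d%s", gene$symbol, pick(alphabet), L + sample(5:50, 1),
                pick(alphabet))
      },
      bad_repeat_index = {
        stopifnot(!is.null(gene$ctd))
        unit <- gene$ctd$unit
        p <- sample(nchar(unit), 1)
        ref <- substr(unit, p, p)
        sprintf("%s-CTD-%s%d%s(r%d)", gene$symbol, ref, p,
                pick(setdiff(chars(AA_LETTERS), ref)),
                gene$ctd$n_repeats + sample(1:10, 1))
      },
      underscore_in_name = sprintf("%s_%s%d", gene$symbol,
                                   pick(letters), sample(1:99, 1)),
      forbidden_char = sprintf("%s-%s%s%d", gene$symbol, pick(c("!", ";", "&", "%")),
                               pick(letters), sample(1:9, 1)),
      missing_locus_for_chimera = {
        stopifnot(!is.null(refdb))
        partner <- refdb[[pick(setdiff(names(refdb), gene$symbol))]]
        sprintf("%s(1-%d)-%s(%d-%d)", gene$symbol, sample(seq(20L, L - 1L), 1),
                partner$symbol, sample(2:10, 1),
                named_length(partner))
      },
      space_in_allele = sprintf("%s %s", gene$symbol,
                                pick(lexicon_tokens(config$lexicon, "tag")))
    )
  }
  list(text = text, defect = if (is.null(defect)) NA_character_ else defect,
       gene = gene$symbol)
}

#' Detect which defect classes an allele text exhibits
#'
#' Runs the parser and reference validation and maps hard errors and
#' error-severity findings onto the seeded defect classes.
#'
#' @param text allele text.
#' @param refdb reference gene set.
#' @param lexicon feature lexicon.
#' @return character vector of detected classes (empty when clean).
#' @export
detect_defects <- function(text, refdb, lexicon = feature_lexicon()) {
  res <- tryCatch({
    a <- parse_allele(text, lexicon = lexicon, genes = names(refdb))
    bind_lints(a$lints, check_allele(a, refdb))
  }, pombelint_parse_error = function(e) e)
  if (is_parse_error(res)) {
    cls <- switch(res$code %||% "parse_error",
                  forbidden_char = "forbidden_char",
                  space_in_allele = "space_in_allele",
                  fusion_requires_locus = "missing_locus_for_chimera",
                  character(0))
    return(cls)
  }
  codes <- unique(res$code[res$severity == "error"])
  intersect(codes, DEFECT_CLASSES)
}

random_clean_genotype <- function(refdb, config) {
  parts <- character(0)
  plasmid_parts <- character(0)  # plasmids serialize after loci
  if (runif(1) < 0.4) parts <- pick(mating_types())
  mix <- config$feature_mix
  n_loci <- sample(1:3, 1)
  used <- character(0)
  for (i in seq_len(n_loci)) {
    sym <- pick(setdiff(names(refdb), used))
    used <- c(used, sym)
    gene <- refdb[[sym]]
    kind <- sample(names(mix), 1, prob = mix)
    L <- named_length(gene)
    piece <- switch(kind,
      wild_type = paste0(sym, "+"),
      deletion = paste0(sym, "Δ"),
      partial_deletion = paste0(sym, clean_partial_deletion_text(gene)),
      edits = paste0(sym, clean_edit_text(gene)),
      ctd = {
        ctd_gene <- refdb[[which(vapply(refdb, function(g) !is.null(g$ctd), TRUE))[1]]]
        if (ctd_gene$symbol %in% used && ctd_gene$symbol != sym) {
          paste0(sym, "+")
        } else {
          used <- c(used, ctd_gene$symbol)
          paste0(ctd_gene$symbol, clean_ctd_text(ctd_gene))
        }
      },
      tags = paste0(sym, "-", pick(lexicon_tokens(config$lexicon, "tag"))),
      markers = paste0(sym, "Δ::", pick(lexicon_tokens(config$lexicon, "marker"))),
      promoters = sprintf("%sΔ::%s-%s-%s:%s", sym,
                          pick(c("P3nmt1", "P41nmt1", "P81nmt1")), sym,
                          pick(lexicon_tokens(config$lexicon, "tag")),
                          pick(lexicon_tokens(config$lexicon, "marker"))),
      plasmid = sprintf("[p%s%d %s-%s]", paste(sample(LETTERS, 3), collapse = ""),
                        sample(1:9, 1),
                        pick(c("P3nmt1", "P41nmt1")), sym),
      diploid = sprintf("%s+/%s", sym, paste0(sym, clean_edit_text(gene, 1L))),
      paste0(sym, "+")
    )
    if (startsWith(piece, "[")) plasmid_parts <- c(plasmid_parts, piece)
    else parts <- c(parts, piece)
  }
  paste(c(parts, plasmid_parts), collapse = " ")
}

#' Generate a strain list with ground truth
#'
#' Rows mix haploid, diploid and plasmid-bearing genotypes built from the
#' reference set. A `defect_rate` fraction of rows (rounded) carries
#' exactly one seeded defect, recorded in the returned truth table.
#'
#' @param config a [generator_config()].
#' @param refdb reference set; built from `config` when omitted.
#' @return list with `rows` (data frame: `strain`, `genotype`) and
#'   `truth` (data frame: `row`, `defect` class or `NA`, `defect_allele`).
#' @export
generate_strain_list <- function(config, refdb = build_reference_db(config)) {
  with_artifact_seed(config$seed, "strain_list", {
    n <- config$n_rows
    genotypes <- vapply(seq_len(n), function(i) {
      random_clean_genotype(refdb, config)
    }, "")
    n_def <- round(n * config$defect_rate)
    defect_rows <- if (n_def > 0) sort(sample.int(n, n_def)) else integer(0)
    truth <- data.frame(row = seq_len(n), defect = NA_character_,
                        defect_allele = NA_character_,
                        stringsAsFactors = FALSE)
    ctd_sym <- names(refdb)[vapply(refdb, function(g) !is.null(g$ctd), TRUE)][1]
    for (r in defect_rows) {
      # a stray space splits an allele into two legal-looking tokens, so it
      # is only detectable on single-allele input, not inside a row
      cls <- pick(setdiff(DEFECT_CLASSES, "space_in_allele"))
      gene <- if (cls == "bad_repeat_index") refdb[[ctd_sym]] else {
        refdb[[pick(setdiff(names(refdb), ctd_sym))]]
      }
      bad <- generate_allele(gene, config, defect = cls, refdb = refdb)
      genotypes[r] <- paste(c(genotypes[r], bad$text), collapse = " ")
      truth$defect[r] <- cls
      truth$defect_allele[r] <- bad$text
    }
    list(rows = data.frame(strain = sprintf("S%04d", seq_len(n)),
                           genotype = genotypes, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write generated fixtures to disk
#'
#' Emits the reference FASTA and metadata TSV, the strain-list TSV and
#' the ground-truth JSON into a directory.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refdb <- build_reference_db(config)
  paths <- c(fasta = file.path(dir, "reference.fasta"),
             metadata = file.path(dir, "reference_metadata.tsv"),
             strains = file.path(dir, "strains.tsv"),
             truth = file.path(dir, "truth.json"))
  write_reference_db(refdb, paths[["fasta"]], paths[["metadata"]])
  gen <- generate_strain_list(config, refdb)
  write.table(gen$rows, paths[["strains"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(gen$truth, paths[["truth"]], dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(paths)
}
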