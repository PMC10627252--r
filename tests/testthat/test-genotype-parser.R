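test_that("tokenizer splits on spaces outside brackets and classifies groups", {
  tk <- tokenize_genotype("h? ura4?")
  expect_identical(tk$tokens$text, c("h?", "ura4?"))
  expect_identical(tk$tokens$type, c("word", "word"))

  tk <- tokenize_genotype("h- ura4-D18 [pXYZ]")
  expect_identical(tk$tokens$text, c("h-", "ura4-D18", "pXYZ"))
  expect_identical(tk$tokens$type, c("word", "word", "plasmid"))

  tk <- tokenize_genotype("[pXYZ P3nmt1-ase1 LEU2] ase1Δ")
  expect_identical(tk$tokens$type, c("plasmid", "word"))
  expect_identical(tk$tokens$text[1], "pXYZ P3nmt1-ase1 LEU2")

  expect_error(tokenize_genotype("[pXYZ"), class = "pombelint_parse_error")
  expect_error(tokenize_genotype("ase1é"), class = "pombelint_parse_error")
})

test_that("unicode lookalikes are normalized with a recorded finding", {
  # U+2212 minus sign instead of the hyphen-minus
  tk <- tokenize_genotype("ase1−GFP")
  expect_identical(tk$tokens$text, "ase1-GFP")
  expect_true("char_normalized" %in% tk$lints$code)

  # superscripts cannot be stored: can1-1^r -> can1-1r, with a warning
  tk <- tokenize_genotype("can1-1ʳ")
  expect_identical(tk$tokens$text, "can1-1r")
  expect_true("superscript" %in% tk$lints$code)
  expect_identical(tk$lints$severity[tk$lints$code == "superscript"], "warning")

  a <- parse_allele("cdc2–5ts")  # en dash
  expect_identical(serialize_allele(a), "cdc2-5ts")
})

test_that("genomic anchors parse and enforce flank adjacency", {
  a <- parse_genomic_anchor("@(CU329670.1:3571861_3571862ins)")
  expect_identical(a$accession, "CU329670.1")
  expect_identical(a$start, 3571861L)
  expect_identical(a$end, 3571862L)
  expect_identical(a$kind, "ins")

  a <- parse_genomic_anchor("@(CU329670.1:1886500_1886750delins)")
  expect_identical(a$kind, "delins")
  expect_identical(a$end - a$start + 1L, 251L)

  expect_error(parse_genomic_anchor("@(X:10_12ins)"),
               class = "pombelint_parse_error")
  expect_error(parse_genomic_anchor("@(X:20_10delins)"),
               class = "pombelint_parse_error")
  expect_error(parse_genomic_anchor("@(10_11ins)"),
               class = "pombelint_parse_error")
})

test_that("every printed allele parses without hard error and round-trips", {
  for (s in golden_alleles()) {
    a <- parse_allele(s)
    expect_s3_class(a, "pomb_allele")
    expect_identical(serialize_allele(a), s)
  }
  for (s in golden_genotypes()) {
    g <- parse_genotype(s)
    expect_identical(serialize_genotype(g), s)
  }
})

test_that("allele structure reflects the locus and linkage semantics", {
  a <- parse_allele("ura4Δ::kanMX6")
  expect_identical(a$locus_side, "left")
  expect_identical(a$locus_kind, "deletion")
  expect_identical(a$left[[1]]$symbol, "ura4")
  expect_identical(a$right[[1]]$token, "kanMX6")
  expect_identical(a$right[[1]]$category, "marker")

  a <- parse_allele("ura4+::P.act1-GFP-ase1")
  expect_identical(a$locus_kind, "wildtype")
  expect_identical(a$right[[1]]$kind, "subcomponent")
  expect_identical(a$right[[1]]$part, "P")
  expect_identical(a$right[[1]]$host, "act1")
  expect_identical(a$right[[2]]$token, "GFP")
  expect_identical(a$right[[3]]$symbol, "ase1")
  expect_identical(a$right[[1]]$link, "-")

  # DAmP-style: three adjacent, functionally unlinked components
  a <- parse_allele("CDS.prp22:natMX6:3UTR.prp22")
  expect_length(a$left, 3)
  expect_identical(vapply(a$left, `[[`, "", "kind"),
                   c("subcomponent", "feature", "subcomponent"))
  expect_identical(a$left[[1]]$link, ":")

  # linker residues vs grouping parentheses
  a <- parse_allele("ase1-(PGAGAGAGS)-GFP")
  expect_identical(a$left[[2]]$kind, "linker")
  expect_identical(a$left[[2]]$residues, "PGAGAGAGS")
  a <- parse_allele("kanMX6:P3nmt1-(ase1-P114PVAL)-GST")
  grp <- a$left[[3]]
  expect_identical(grp$kind, "group")
  expect_identical(grp$components[[1]]$symbol, "ase1")

  # provenance prefixes
  a <- parse_allele("ura4+::Scer\\ACT1-GFP")
  expect_identical(a$right[[1]]$provenance, "Scer")
  expect_identical(a$right[[1]]$token, "ACT1")

  # trailing-marker form: the construct names its own (endogenous) locus
  a <- parse_allele("ase1-GFP::ura4+")
  expect_identical(a$locus_side, "right")

  # bare locus before '::' is ambiguous (wild type or deleted?)
  a <- parse_allele("ura4::ase1-GFP")
  expect_true("ambiguous_locus" %in% a$lints$code)
  # ...except for anchored disruption alleles
  a <- parse_allele("ase1::kanMX6@(CU329670.1:1878390_1878391ins)")
  expect_identical(a$locus_kind, "disruption")

  # implied endogenous locus (single host gene plus nonvariant features)
  expect_true(parse_allele("mCherry-atb2:kanMX6")$endogenous)
  expect_false(parse_allele("cdc25-C480S")$endogenous)
})

test_that("fusions and chimeras without an insertion locus are rejected", {
  expect_error(parse_allele("ase1(1-130)-mal3(4-190)"),
               class = "pombelint_parse_error")
  expect_error(parse_allele("mal3-ase1"), class = "pombelint_parse_error")
  a <- parse_allele("ase1Δ::ase1(1-130)-mal3(4-190):kanMX6")
  expect_s3_class(a, "pomb_allele")
  expect_error(parse_allele("ase1 GFP"), class = "pombelint_parse_error")
  expect_error(parse_allele("ura4Δ::kanMX6::ase1"),
               class = "pombelint_parse_error")
})

test_that("genotypes aggregate mating type, diploid loci and plasmids", {
  g <- parse_genotype("h? ura4?")
  expect_identical(g$mating_type, "h?")
  expect_length(g$loci, 1)
  expect_identical(g$loci[[1]]$alleles[[1]]$left[[1]]$features[[1]]$type,
                   "unknown")

  g <- parse_genotype("ura4+/ura4-294")
  expect_true(g$loci[[1]]$diploid)
  expect_identical(g$loci[[1]]$alleles[[1]]$left[[1]]$features[[1]]$type,
                   "wild_type")
  expect_identical(g$loci[[1]]$alleles[[2]]$left[[1]]$features[[1]]$text, "294")

  g <- parse_genotype("h- ura4-D18 [pXYZ]")
  expect_identical(g$mating_type, "h-")
  expect_identical(g$plasmids[[1]]$name, "pXYZ")

  g <- parse_genotype("[pXYZ pREP3\\P3nmt1-mCherry-ase1-pREP3\\T.nmt1:LEU2]")
  expect_length(g$plasmids[[1]]$elements, 1)
  el <- g$plasmids[[1]]$elements[[1]]
  expect_identical(el$left[[1]]$provenance, "pREP3")

  expect_length(parse_genotype("")$loci, 0)
  expect_identical(serialize_genotype(parse_genotype("")), "")

  # '::' is not accepted inside plasmid element lists
  expect_error(parse_genotype("[pXYZ ura4Δ::kanMX6]"),
               class = "pombelint_parse_error")
})

test_that("hyphens inside parentheses never split components", {
  withr::with_seed(31, {
    tags <- c("GFP", "mCherry", "GST")
    for (i in 1:1000) {
      sym <- paste0(paste(sample(letters, 3, TRUE), collapse = ""),
                    sample(1:99, 1))
      a <- sample.int(200, 1); b <- a + sample.int(300, 1)
      form <- switch(sample(4, 1),
        sprintf("%sΔ(%d-%d)-%s", sym, a, b, sample(tags, 1)),
        sprintf("%s(%d-%d,%d-%d)", sym, a, b, b + 2, b + sample.int(50, 1) + 2),
        sprintf("%s-(%s)-%s", sym, rand_aa(sample(3:12, 1)), sample(tags, 1)),
        sprintf("%s-CTD-Y1F(r%d-r%d)", sym, a %% 20 + 1, a %% 20 + 5)
      )
      parsed <- parse_allele(form)
      expect_identical(serialize_allele(parsed), form)
    }
  })
})

test_that("generated genotypes round-trip through parse and serialize", {
  cfg <- generator_config(seed = 404, n_rows = 300)
  db <- build_reference_db(cfg)
  gen <- generate_strain_list(cfg, db)
  for (text in gen$rows$genotype) {
    g <- parse_genotype(text, genes = names(db))
    expect_identical(serialize_genotype(g), text)
  }
})
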