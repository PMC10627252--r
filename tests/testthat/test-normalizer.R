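test_that("legacy tokens harmonize to the recommended names", {
  expect_identical(as.character(harmonize_token("P3Xnmt1")), "P3nmt1")
  expect_identical(as.character(harmonize_token("P3-nmt1")), "P3nmt1")
  expect_identical(as.character(harmonize_token("Pnmt1")), "P3nmt1")
  expect_identical(as.character(harmonize_token("P41Xnmt1")), "P41nmt1")
  expect_identical(as.character(harmonize_token("P81-nmt1")), "P81nmt1")
  expect_identical(as.character(harmonize_token("kanr")), "kanMX6")
  expect_identical(as.character(harmonize_token("natr")), "natMX6")
  expect_identical(as.character(harmonize_token("hygr")), "hphMX6")
  expect_identical(as.character(harmonize_token("bler")), "bleMX6")
  expect_identical(as.character(harmonize_token("ase1_x1")), "ase1-x1")
  expect_false(is.null(attr(harmonize_token("ase1_x1"), "note")))

  # legacy period short names are recognized but not renamed
  h <- harmonize_token("cut12.s11")
  expect_identical(as.character(h), "cut12.s11")
  expect_match(attr(h, "note"), "not renamed")

  # recommended names are fixpoints
  for (t in c("P3nmt1", "P41nmt1", "P81nmt1", "kanMX6", "natMX6", "hphMX6",
              "bleMX6", "GFP", "ase1-x1")) {
    h <- harmonize_token(t)
    expect_identical(as.character(h), t)
    expect_false(isTRUE(attr(h, "changed")))
  }
  # and harmonization is idempotent on every table entry
  tab <- harmonization_table()
  for (rec in unique(tab$recommended)) {
    expect_identical(as.character(harmonize_token(rec)), rec)
  }
})

test_that("canonicalization rewrites the printed equivalent forms", {
  db <- toy_refdb()
  # retained-mode deletions become removed-mode given the reference length
  expect_identical(
    serialize_allele(canonicalize_allele("ase1(1-113)", refdb = db)),
    "ase1Δ(114-731)")
  expect_identical(
    serialize_allele(canonicalize_allele("ase1(1-19,115-529)", refdb = db)),
    "ase1Δ(20-114,530-731)")
  # no reference: left in retained mode
  expect_identical(
    serialize_allele(canonicalize_allele("ase1(1-113)")),
    "ase1(1-113)")

  # implied endogenous locus is materialized
  expect_identical(
    serialize_allele(canonicalize_allele("mCherry-atb2:kanMX6")),
    "atb2Δ::mCherry-atb2:kanMX6")

  # legacy component tokens are harmonized in place
  expect_identical(
    serialize_allele(canonicalize_allele("ase1Δ::kanr")),
    "ase1Δ::kanMX6")

  # underscore short names are rewritten to hyphens
  expect_identical(serialize_allele(canonicalize_allele("ase1_x1")), "ase1-x1")

  # flanking-locus forms collapse onto a fixed orientation
  expect_identical(
    serialize_allele(canonicalize_allele("ura4-294::P.ase1-ase1-GFP:ura4+")),
    serialize_allele(canonicalize_allele("ura4+::P.ase1-ase1-GFP:ura4-294")))
})

test_that("canonicalization is idempotent", {
  db <- toy_refdb()
  cases <- c("ase1(1-113)", "mCherry-atb2:kanMX6", "ase1Δ::kanr", "ase1_x1",
             "ura4-294::P.ase1-ase1-GFP:ura4+", "cdc25-C480S",
             "rpb1-CTD-Y1F(r1-r12)", "P3Xnmt1-ase1-GFP:kanr",
             golden_alleles())
  for (s in cases) {
    once <- canonicalize_allele(s, refdb = db)
    twice <- canonicalize_allele(once, refdb = db)
    expect_identical(serialize_allele(twice), serialize_allele(once))
  }
})

test_that("canonicalization preserves reference-validation findings", {
  db <- toy_refdb()
  ref_codes <- c("residue_mismatch", "out_of_range", "bad_repeat_index")
  cases <- c("ase1-G114A", "ase1-P800A", "rpb1-CTD-Y1F(r30)",
             "ase1-P114A,Q117A", "ase1(1-113)", "rpb1-CTD-Y1F")
  for (s in cases) {
    a <- parse_allele(s, genes = names(db))
    before <- sort(intersect(check_allele(a, db)$code, ref_codes))
    after <- sort(intersect(check_allele(canonicalize_allele(a, refdb = db),
                                         db)$code, ref_codes))
    expect_identical(after, before)
  }
})

test_that("synonymy matches the printed equivalences", {
  db <- toy_refdb()
  expect_true(are_synonymous("ura4+::P.ase1-ase1-GFP:ura4-294",
                             "ura4-294::P.ase1-ase1-GFP:ura4+"))
  expect_true(are_synonymous("ase1Δ(20-114,530-731)", "ase1(1-19,115-529)",
                             refdb = db))
  expect_true(are_synonymous("ase1(1-113)", "ase1Δ(114-731)", refdb = db))
  expect_true(are_synonymous("mCherry-atb2:kanMX6",
                             "atb2Δ::mCherry-atb2:kanMX6"))
  expect_false(are_synonymous("ase1-P114A", "ase1-P114G"))
  # the marker is part of the structure: different constructions differ
  expect_false(are_synonymous("ura4Δ", "ura4Δ::kanMX6"))
})

test_that("synonymy is an equivalence relation on generated families", {
  db <- toy_refdb()
  seqs <- db[["ase1"]]
  withr::with_seed(51, {
    families <- lapply(1:150, function(i) {
      kind <- sample(3, 1)
      if (kind == 1) {
        # retained vs removed partial deletion of ase1 (length 731)
        a <- sample.int(600, 1) + 1L
        b <- a + sample.int(100, 1)
        c(sprintf("ase1Δ(%d-%d)", a, b),
          sprintf("ase1(1-%d,%d-731)", a - 1L, b + 1L))
      } else if (kind == 2) {
        # implied endogenous locus vs materialized form
        tag <- sample(c("GFP", "mCherry", "GST"), 1)
        mk <- sample(c("kanMX6", "natMX6"), 1)
        c(sprintf("%s-ase1:%s", tag, mk),
          sprintf("ase1Δ::%s-ase1:%s", tag, mk))
      } else {
        # flanking-locus orientation swap
        tag <- sample(c("GFP", "mCherry"), 1)
        sn <- sample.int(999, 1)
        c(sprintf("ura4+::P.ase1-ase1-%s:ura4-%d", tag, sn),
          sprintf("ura4-%d::P.ase1-ase1-%s:ura4+", sn, tag))
      }
    })
    for (fam in families) {
      # reflexive, symmetric, and equal within the family
      expect_true(are_synonymous(fam[1], fam[1], refdb = db))
      expect_true(are_synonymous(fam[1], fam[2], refdb = db))
      expect_true(are_synonymous(fam[2], fam[1], refdb = db))
    }
    # transitivity across three surface forms of one allele
    tri <- c("ase1Δ(100-200)", "ase1(1-99,201-731)", "ase1Δ(100-200)")
    expect_true(are_synonymous(tri[1], tri[2], refdb = db) &&
                are_synonymous(tri[2], tri[3], refdb = db) &&
                are_synonymous(tri[1], tri[3], refdb = db))
    # across families: not synonymous
    for (i in 1:30) {
      f1 <- sample(families, 1)[[1]]
      f2 <- sample(families, 1)[[1]]
      if (identical(f1, f2)) next
      expect_false(are_synonymous(f1[1], f2[2], refdb = db))
    }
  })
})

test_that("flanking-form enumeration lists exactly the accepted synonyms", {
  forms <- enumerate_flanking_forms("ura4+::P.ase1-ase1-GFP:ura4-294")
  expect_length(forms, 2)
  expect_setequal(forms, c("ura4+::P.ase1-ase1-GFP:ura4-294",
                           "ura4-294::P.ase1-ase1-GFP:ura4+"))
  expect_true(are_synonymous(forms[1], forms[2]))
  # a deletion locus flanks nothing
  expect_length(enumerate_flanking_forms("ase1Δ::kanMX6"), 1)
})
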