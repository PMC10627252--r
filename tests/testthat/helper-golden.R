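# Allele and genotype strings printed in the nomenclature guidelines
# (variant-feature table, nonvariant-feature table, the numbered rules and
# the figure legend), used for conformance and round-trip checks.

golden_alleles <- function() c(
  # variant features
  "ase1+", "ase1Δ", "ase1(1-35)", "ase1(1-35,40-700)",
  "ase1Δ(114-120)", "ase1Δ(114-120,150-200)", "ase1(1-113)",
  "ase1Δ(114-731)", "ase1Δ(20-114,530-731)", "ase1(1-19,115-529)",
  "ase1-P114A,Q117A", "ase1-P114*", "ase1-PLI114AAA", "ase1-PLI114LAVKK",
  "ase1-PLI114VPAAL", "ase1-P114PVAL", "ase1-P114PVPAL",
  "ase1Δ(20-30)-P114A,E126A", "ase1-35",
  "ase1::kanMX6@(CU329670.1:1878390_1878391ins)",
  # CTD repeats
  "rpb1-CTD-Y1F", "rpb1-CTD-Y1F(r1,r2)", "rpb1-CTD-Y1F(r1-r12)",
  "rpb1-CTD-Δ(r11-r29)", "rpb1-CTD-Y1F(r1-r29-2)",
  "rpb1-CTD-S5A(r1-r12),Δ(r13-r29)", "rpb1-N494D-CTD-Δ(r11-r29)",
  "rpb1-N494D-CTD-Y1F(r1-r12)", "rpb1-S2A,N494D-CTD-Y1F,S5A",
  # transcripts and short names
  "zas1.2-R89A", "ura4-D18", "ade6-M210", "arg1-230", "can1-1r", "cdc2-5ts",
  # nonvariant features and special characters
  "ura4-", "ura4?", "ura4+::ase1-GFP", "ase1Δ::kanMX6",
  "ura4Δ::P3nmt1-GFP-ase1", "ura4+::ase1-GFP:ura4-294",
  "CDS.prp22:natMX6:3UTR.prp22", "ura4+::P.act1-GFP-ase1-T.ase1",
  "P3nmt1-ase1-GFP-T.nmt1:kanMX6", "ase1Δ::ase1-mal3:kanMX6",
  "ase1Δ::ase1(1-130)-mal3(4-190):kanMX6", "kanMX6:P3nmt1-ase1-GFP",
  "ura4Δ::P.ase1-ase1-GFP:P.atb2-mCherry-atb2:kanMX6",
  "ura4+::P.ase1-ase1-GFP-T.ase1:P.atb2-mCherry-atb2-T.atb2:kanMX6",
  "ura4+::loxP:ase1-GFP:loxP:kanMX6",
  "ura4::kanMX6@(CU329670.1:3571861_3571862ins)",
  "P3nmt1-ase1-GFP-T.nmt1:kanMX6@(CU329670.1:1886500_1886750delins)",
  "ura4+::Scer\\ACT1-GFP", "ase1-pXYZ\\meGFP:kanMX6", "ase1-SV40\\NLS:kanMX6",
  "ase1-(PGAGAGAGS)-GFP", "ase1-linker-GFP",
  "kanMX6:P3nmt1-(ase1-P114PVAL)-GST",
  # endogenous-locus equivalence and figure-legend forms
  "mCherry-atb2:kanMX6", "atb2Δ::mCherry-atb2:kanMX6",
  "ase1-GFP::ura4+", "ura4+::P.ase1-ase1-GFP:ura4-294",
  "ura4-294::P.ase1-ase1-GFP:ura4+",
  "ura4Δ::P.ase1-CFP-ase1-T.ase1:ura4+:P.atb2-GFP-atb2-T.atb2",
  "cdc25-C480S", "cdc25-GFP", "cdc25-C480S-GFP"
)

golden_genotypes <- function() c(
  "h? ura4?", "ura4+/ura4-294", "h- ura4-D18 [pXYZ]", "ura4 [pXYZ]",
  "GFP-ase1-IAA17 ura4+::Atal\\TIR1",
  "[pXYZ pREP3\\P3nmt1-mCherry-ase1-pREP3\\T.nmt1:LEU2]"
)

# -- random variant-suffix generator for the regex/parser agreement and
#    round-trip properties ---------------------------------------------------

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

rand_ranges <- function() {
  k <- sample(1:3, 1)
  bounds <- sort(sample.int(900, 2 * k))
  paste(sprintf("%d-%d", bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)]),
        collapse = ",")
}

rand_edit <- function() {
  sprintf("%s%d%s%s", rand_aa(sample(1:3, 1)), sample.int(900, 1),
          rand_aa(sample(1:3, 1)), if (runif(1) < 0.15) "*" else "")
}

rand_edits <- function() {
  paste0("-", paste(replicate(sample(1:3, 1), rand_edit()), collapse = ","))
}

rand_selector <- function() {
  k <- sample(1:2, 1)
  parts <- replicate(k, {
    a <- sample.int(28, 1)
    if (runif(1) < 0.4) sprintf("r%d", a)
    else if (runif(1) < 0.5) sprintf("r%d-r%d", a, a + sample.int(10, 1))
    else sprintf("r%d-r%d-%d", a, a + sample.int(10, 1), sample(2:4, 1))
  })
  sprintf("(%s)", paste(parts, collapse = ","))
}

rand_ctd <- function() {
  items <- replicate(sample(1:2, 1), {
    head <- switch(sample(3, 1),
                   "Δ",
                   sprintf("Δ(%s)", rand_ranges()),
                   rand_edit())
    paste0(head, if (runif(1) < 0.6) rand_selector() else "")
  })
  paste0("-CTD-", paste(items, collapse = ","))
}

rand_valid_suffix <- function() {
  switch(sample(8, 1),
    "+",
    "Δ",
    sprintf("(%s)", rand_ranges()),
    sprintf("Δ(%s)", rand_ranges()),
    rand_edits(),
    paste0(sprintf("Δ(%s)", rand_ranges()), rand_edits()),
    rand_ctd(),
    paste0(rand_edits(), rand_ctd())
  )
}

corrupt_suffix <- function(s) {
  cs <- strsplit(s, "")[[1]]
  op <- sample(7, 1)
  if (op == 1) return(paste0(s, ","))
  if (op == 2) return(paste0(s, " "))
  if (op == 3) return(sub("[A-Z]", "B", s))          # letter outside alphabet
  if (op == 4) return(sub("[A-Z]", "y", s))          # lowercase residue
  if (op == 5 && length(cs) > 1) {
    i <- sample(length(cs), 1)
    return(paste(cs[-i], collapse = ""))             # drop one character
  }
  if (op == 6) return(paste0(s, "-"))
  paste0(sample(c("-", ","), 1), s)
}

# Mix of valid, corrupted and free-form strings; NULL product of the
# agreement property is that regex and parser never disagree.
rand_suffix_corpus <- function(n, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      r <- runif(1)
      if (r < 0.45) rand_valid_suffix()
      else if (r < 0.8) corrupt_suffix(rand_valid_suffix())
      else {
        # free-form short-name-like or junk tokens
        paste0(sample(c("-", "", "Δ", "("), 1),
               paste(sample(c(letters, LETTERS, 0:9, "-", ",", "(", ")"),
                            sample(2:8, 1), replace = TRUE), collapse = ""))
      }
    }, "")
  })
}
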