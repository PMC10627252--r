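Package: pombelint
Title: Parse, Validate and Canonicalize Fission-Yeast Gene and Genotype Nomenclature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Schizosaccharomyces pombe gene symbols,
    allele names and strain genotypes under the revised PomBase nomenclature
    guidelines. Provides a structured parser and serializer for genotype
    strings and allele variant-feature suffixes (partial deletions,
    substitutions, insertions, CTD tandem-repeat edits, markers, tags,
    promoters and insertion loci), sequence-aware validation of alleles
    against a reference gene set, harmonization of legacy naming variants,
    canonicalization and synonym detection, a seeded generator of synthetic
    reference sets and strain lists with labelled defects, and a
    command-line linter for strain lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
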