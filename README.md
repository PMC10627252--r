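# pombelint

Parsing, validation and canonicalization of fission-yeast gene and
genotype nomenclature.

Strain lists in *Schizosaccharomyces pombe* papers describe tens of
engineered alleles — point mutants, deletions, tags, promoter swaps,
marker cassettes, chimeras — in a compact string syntax. Community
guidelines (curated with PomBase) fix that syntax precisely so that
genotypes become machine-readable: gene symbols are three lowercase
letters plus digits; noncoding RNA genes borrow the regulated gene's
symbol plus a relationship suffix (`ase1-as1`, `ase1-dt`); variant
features are written against the wild-type product sequence
(`ase1Δ(114-120)`, `ase1-PLI114AAA`, `rpb1-CTD-Y1F(r1-r12)`); nonvariant
features are chained with `-` (functionally linked) and `:` (adjacent),
anchored to an insertion locus with `::`, and optionally pinned to exact
chromosome coordinates with `@(accession:start_end[del]ins)`.

`pombelint` implements that grammar end to end, for curators, tool
builders and anyone maintaining a strain collection:

* **parse / serialize** — genotype strings to structured records and
  back, losslessly (`parse_genotype()`, `parse_allele()`,
  `serialize_genotype()`), with precise errors for disallowed
  characters, spaces in allele names, unbalanced brackets, double `::`
  and locus-less fusions.
* **validate** — sequence-aware linting against a reference gene set
  (`check_allele()`, `lint_strain_list()`): replaced residues are
  compared with the reference sequence (with the histone numbering
  convention — positions count from after the removed initiator Met),
  deletion ranges and CTD repeat indices are bounds-checked, RNA-gene
  variants must use DNA letters, and style deviations (superscripts,
  underscores, `ΔN`/`ΔC` truncation names, legacy period separators)
  are flagged at warning level.
* **canonicalize / synonyms** — one preferred surface form per allele
  (`canonicalize_allele()`, `are_synonymous()`): retained-mode partial
  deletions become `Δ` form via range complementation, legacy tokens are
  harmonized (`P3Xnmt1` → `P3nmt1`, `kanr` → `kanMX6`), the implied
  endogenous locus is materialized (`mCherry-atb2:kanMX6` ≡
  `atb2Δ::mCherry-atb2:kanMX6`), and flanking-marker constructs
  (`ura4+::…:ura4-294` ≡ `ura4-294::…:ura4+`) compare equal.
* **generate** — seeded synthetic reference sets and strain lists with
  labelled single defects (`build_reference_db()`,
  `generate_strain_list()`), for testing pipelines without downloads.
* a **command-line linter** (`inst/cli/pombelint.R`) with `lint`,
  `canonicalize`, `generate` and `explain` subcommands and conventional
  exit codes (0 clean / 1 findings / 2 usage).

The variant-feature grammar is recognized twice, independently: by a
recursive-descent parser and by an assembled anchored regular expression
shipped with the package (`variant_suffix_regex()`, built from the
published per-variant-type pattern table in
`inst/extdata/variant_regex.tsv`). The two recognizers are required to
agree, which is enforced by a 10,000-case generated-corpus test.

## Worked example

```r
library(pombelint)

run_explain("ura4Δ::P3nmt1-GFP-ase1")
#> ura4Δ::P3nmt1-GFP-ase1
#>   insertion locus (rule '::'): ura4Δ [deletion]
#>   regulatory: P3nmt1 -- '-' functionally linked to next
#>   tag: GFP -- '-' functionally linked to next
#>   gene ase1: gene product (wild-type sequence)
```

The `ura4` open reading frame was replaced by a construct expressing
GFP-tagged Ase1 from the full-strength `nmt1` promoter: the locus is
written first (`ura4Δ::` — deleted, not just interrupted), and every
component is functionally linked to the next.

Sequence-aware validation catches the error class the nomenclature
exists to prevent — an allele citing a residue that is not there:

```r
db <- new_refdb(list(new_ref_gene("ase1", "SPAPB1A10.09", "protein",
  paste0("M", strrep("A", 112), "PLIQ", strrep("A", 614)))))
check_allele(parse_allele("ase1-P113A", genes = "ase1"), db)
#> error   residue_mismatch    ase1: reference mismatch P≠A@113
```

Here the proline actually sits at position 114, so naming it `P113A`
yields an error-severity finding with the reference residue (`A`) at the
cited position. Canonicalization and synonym detection:

```r
serialize_allele(canonicalize_allele("mCherry-atb2:kanMX6"))
#> [1] "atb2Δ::mCherry-atb2:kanMX6"
are_synonymous("ura4+::P.ase1-ase1-GFP:ura4-294",
               "ura4-294::P.ase1-ase1-GFP:ura4+")
#> [1] TRUE
```

The first call materializes the endogenous locus implied by a name that
contains a single host gene; the second recognizes the two accepted
orders of a flanking-marker integration as the same allele.

## Command line

```sh
Rscript inst/cli/pombelint.R generate --out fixtures --seed 1 --n 50
Rscript inst/cli/pombelint.R lint --input fixtures/strains.tsv \
    --reference fixtures/reference.fasta --metadata fixtures/reference_metadata.tsv
Rscript inst/cli/pombelint.R explain 'ase1Δ(20-30)-P114A,E126A'
```

## Package layout

| | |
|---|---|
| `R/symbols.R` | gene-symbol validation, ncRNA classes, proposals |
| `R/variant_grammar.R` | variant-suffix parser/serializer, range algebra, CTD selectors |
| `R/regex.R` | assembled regular-expression recognizer |
| `R/genotype_parser.R` | tokenizer, allele/genotype parser and serializer |
| `R/reference_check.R` | reference gene sets (FASTA + TSV), sequence-aware lints |
| `R/normalizer.R` | harmonization, canonicalization, synonymy |
| `R/fixtures.R` | seeded generators and defect injection |
| `R/cli.R`, `inst/cli/` | command-line workflows |
| `inst/extdata/` | editable lexica: symbol exceptions, feature tokens, harmonization table, published regex table, lint codes |

See the methods vignette (`vignettes/genotype-nomenclature.Rmd`) for the
grammar, the validation model and the design decisions.
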