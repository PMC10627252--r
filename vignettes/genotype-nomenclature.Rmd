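---
title: "A grammar for fission-yeast genotype nomenclature: parsing, validation and canonicalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grammar for fission-yeast genotype nomenclature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombelint)
```

## The problem

A fission-yeast genotype is a line of text naming every allele in a
strain that differs from the wild-type reference. The community
nomenclature fixes this text precisely enough to be machine readable,
and that precision is what makes three things possible: detecting
errors (an allele citing a residue that is not at the stated position),
harmonizing the many historical spellings of the same component, and
recognizing that two differently written names denote the same allele.
`pombelint` implements the grammar, the sequence-aware validator, and
the canonicalizer, plus a seeded generator that makes the whole stack
testable without network access.

## The grammar and how it is parsed

An allele name is a chain of components. Three separators carry the
structure, and their binding strength is the first real design
decision:

* `::` marks the insertion locus and is handled first (at most one per
  name; two are a hard error).
* `:` joins components that are adjacent but not functionally linked
  (markers, recombination sites, tandem products). It binds loosest.
* `-` joins functionally linked components (tag fused to a product,
  promoter driving it). It binds tightest of the separators, but
  hyphens *inside* parentheses (residue ranges, linkers, repeat
  selectors) and inside matched variant suffixes are never separators.

Rather than splitting on separators globally — which is impossible,
since `-` is also part of gene symbols (`mat1-Mc`), short names
(`ura4-D18`) and suffixes (`-P114A`) — the parser scans left to right,
classifying each element in a fixed order: known gene symbol (longest
match, including hyphenated ncRNA symbols and transcript-qualified
`zas1.2` forms) with a maximal variant suffix; gene-structure
subcomponent (`P.`, `T.`, `CDS.`, `5UTR.`, `3UTR.`, `intronN.`);
`\`-provenance-prefixed feature (`Scer\ACT1`, `SV40\NLS`); lexicon
feature (tags, markers, promoters, recombination sites, encoded tools);
parenthesized linker or grouping; and finally the short-name fallback.
The known-symbol set matters only for hyphenated symbols — anything
matching the classic three-letters-plus-digits pattern or a
systematic-identifier prefix is recognized as a gene without it.

The variant suffix itself (`+`, `Δ`, `Δ(114-120,150-200)`, `(1-113)`,
`-P114A,Q117A`, `-CTD-S5A(r1-r12),Δ(r13-r29)`) is matched greedily:
candidate cut points are the top-level `-`/`:` positions after the gene
symbol, tried longest first. This is what keeps `ase1-P114A-GFP` parsing
as an edit plus a tag while `ase1-GFP` parses as a tag and `ase1-35` as
a short name.

### Syntax versus semantics

The package recognizes the suffix grammar twice: a recursive-descent
parser, and an assembled anchored regular expression built from the
published per-variant-type pattern table (shipped verbatim in
`inst/extdata/variant_regex.tsv`). A regular expression cannot see
constraints like "ranges ascend", "edits must not touch the same
residues" or "`*` only ends a replacement", so those are *semantic*
errors, raised only after the whole suffix has been consumed
syntactically. Agreement between the two recognizers is then defined
over syntax — a semantically invalid but well-formed suffix is
"recognized" by both — and enforced on a 10,000-string generated corpus
mixing valid forms, systematic corruptions (stray commas, spaces,
lowercase residues, letters outside the alphabet, deleted characters)
and free-form junk. Two deliberate deviations from the printed pattern
table: the repeat selector also accepts the comma list form
(`(r1,r2)`) that the prose rules allow, and residue classes are
restricted to the 20 amino-acid letters (or `ACGT` for RNA genes, which
write variants in DNA letters, `T` rather than `U`) as the table's own
footnote recommends.

### Coordinates and conventions

All coordinates are 1-based and inclusive; index 1 is the initiator
methionine, except for histone genes, where the community convention
numbers residues after Met removal, so named position *k* reads
sequence position *k + 1*. Edits always refer to the reference
sequence, never to the post-edit sequence, which is why overlapping
edits are rejected outright. An insertion is written by repeating the
flanking residue (`P114PVAL`); detection therefore requires a
single-residue `replaced` that prefixes a longer replacement, and
longer replaced strings with a prefix match are classified as
deletion–insertions. CTD tandem-repeat edits are positions within the
repeat unit plus optional repeat selectors `rN`, `rN-rM`, `rN-rM-step`
(default step 1, step > 1 only with an explicit range); the CTD block
always serializes last because commas are ambiguous otherwise.

### Locus semantics

`A::B` is disambiguated structurally: if the left side is a single
allele of a host gene it is the insertion locus (`ura4Δ::kanMX6`,
`ura4+::ase1-GFP`); otherwise, if the right side is a bare host-gene
allele, the name is the construct-first form whose own single host gene
names the endogenous locus (`ase1-GFP::ura4+`). A bare symbol before
`::` (`ura4::ase1-GFP`) parses but draws a warning — it does not say
whether the locus allele survived — except for anchored disruptions
(`ase1::kanMX6@(...)`), where only the locus may be given. A name
containing two host-gene elements and no `::` is a hard error: for
fusions and chimeras the insertion locus is compulsory, since it
decides whether a wild-type copy of either gene remains.

## Validation model

Findings are lints with a stable code, a severity, a character span and
an optional suggested fix (`lint_codes()` enumerates them). Severities
follow one rule: *reference disagreements and structural violations are
errors; discouraged but legal style is a warning; normalizations are
informational.* Reference checks compare only the `replaced` letters of
an edit — replacements are engineered sequence and unconstrained. For
CTD edits the wild-type residue is checked against the repeat unit and
selectors against the repeat count; mapping to absolute protein
coordinates (region start + (repeat − 1) × unit length + position − 1)
is only possible when the reference records where the repeat region
starts, so unit- and count-level checks are the default. Transcript
selection is by name: a bare symbol checks against the primary
transcript, `gene.N` against transcript *N*.

Character handling is conservative: the only permitted non-ASCII
character is `Δ`. Unicode lookalikes that word processors introduce
(minus sign, en/em dashes, no-break space) are normalized with an
info-level lint each; superscript characters are flattened with a
warning (they cannot be stored in plain-text databases); everything
else non-ASCII is a hard error. The strings `delta` and `(del)` are
*not* auto-mapped to `Δ` — too ambiguous — and draw no rewrite.

## Canonicalization and synonymy

Canonical form is computed structurally, and `are_synonymous()` is
simply equality of canonical serializations — which makes it an
equivalence relation by construction. The rewrites, in order:

1. legacy tokens are harmonized from an editable table (`P3-nmt1`,
   `P3Xnmt1`, `Pnmt1` → `P3nmt1`; `kanr`-style resistance names →
   `kanMX6`-family cassettes); underscores in short names become
   hyphens (the original spelling is kept as a synonym), while legacy
   period separators (`cut12.s11`) are recognized but never renamed;
2. retained-mode partial deletions become removed-mode (`Δ`) by range
   complementation when the reference length is known — the `Δ` form
   is preferred because it shows the modification — and are left
   untouched (with a note) otherwise;
3. a name with a single host gene and nonvariant features is
   materialized at its endogenous locus
   (`mCherry-atb2:kanMX6` → `atb2Δ::mCherry-atb2:kanMX6`);
4. flanking-locus synonym pairs collapse onto one orientation: the
   form whose pre-`::` allele text sorts first in a fixed (C-locale,
   radix) order leads. The guidelines declare the two forms equal
   without preferring one, so the tie-break is ours and is documented
   here; both forms remain accepted on input and are enumerable with
   `enumerate_flanking_forms()`.

Deliberate non-equivalences: `ura4Δ` and `ura4Δ::kanMX6` are distinct
(the marker is part of the locus structure), and plasmid-borne versus
integrated copies of a construct are distinct strings.

## The synthetic generator

`build_reference_db()` emulates just enough of a real gene set to
exercise every validation path: random protein sequences starting with
Met in a configurable length range (default 200–800 residues, typical
of yeast proteins), one histone-numbered gene, one CTD gene carrying
29 tandem `YSPTSPS` repeats (the repeat unit and count of the RNA
polymerase II large subunit) at a recorded offset, one RNA gene and one
two-transcript gene. It makes no attempt to mimic real amino-acid
composition, codon usage or homology — so passing tests demonstrate
grammar and validator correctness, not performance on real PomBase
sequences, whose symbols, exception names and edge cases are richer
than the generator's classic-pattern symbols.

Strain lists mix haploid, diploid and plasmid entries from a weighted
feature mix; a configured fraction of rows carries exactly one labelled
defect from seven classes (wrong reference residue, out-of-range
position, bad repeat index, underscore in a short name, forbidden
character, locus-less chimera, space inside an allele). Each artifact
draws from its own pseudo-random stream keyed by (seed, artifact name),
so outputs are byte-identical under a seed and adding a generator does
not shift the others. A stray space is only detectable on single-allele
input — inside a row it simply splits into two legal-looking tokens —
so that class is excluded from row-level injection and measured on the
allele-level corpus.

## Problem sizes and verification

The test suite verifies, at these sizes: round-trip identity
(parse–serialize) on 10,000 generated genotypes; parser/regex agreement
on 10,000 generated suffixes; complement involution on 10,000 random
range sets (canonical ranges, i.e. separated by at least one retained
residue — touching ranges would merge and are never written); 100%
defect recall and precision per class on 1,000 seeded cases;
canonicalization idempotence and synonymy on generated families; and
parse-plus-round-trip of every allele and genotype string printed in
the guidelines. The complete suite runs in a few minutes on one CPU.

## Resolved ambiguities and limitations

* ncRNA indices: validation accepts gaps (`ase1-ot3` without
  `ase1-ot2`); only the proposal operation fills the next free index.
* `h90` is included in the mating-type lexicon alongside `h+`, `h-`,
  `h?` — standard community usage even where lists omit it.
* `?` attaches to gene symbols and `h` only; `::` is rejected inside
  plasmid element lists; both are conservative readings of unstated
  cases.
* Retained-mode groups may combine with comma-joined edits by analogy
  with the removed-mode combination; the serialized order is deletion,
  edits, CTD.
* A suffix that fails the structured grammar but is a single
  letters/digits token is a legal short name, even when it looks like
  a malformed edit — `ase1-G57S` on an RNA gene is a short name, not an
  alphabet error; only structurally unambiguous violations are hard
  errors.
* Genomic anchors are validated for shape and flank adjacency only;
  checking coordinates against chromosome sequences would require the
  assemblies themselves and is out of scope, as is any retrieval of
  real PomBase data: reference sets are user-supplied FASTA + metadata
  or generated.
* Transcription orientation of inserted constructs is deliberately not
  represented — the same name covers either orientation, by rule.
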