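# Stable identifiers for findings emitted by the validators.
code	severity	meaning
forbidden_char	error	character outside the allowed set (Latin letters, digits, allowed symbols, Greek Delta)
space_in_allele	error	whitespace inside an allele name
unbalanced_bracket	error	unmatched parenthesis or square bracket
parse_error	error	name does not match the genotype grammar
fusion_requires_locus	error	gene fusion or chimera written without an insertion locus
double_insertion_locus	error	more than one '::' in an allele name
residue_mismatch	error	replaced residue differs from the reference sequence at that position
out_of_range	error	position or range beyond the reference product length
bad_repeat_index	error	CTD repeat index beyond the repeat count (or not ascending)
underscore_in_name	error	underscore in an allele variant short name
rna_letters	error	RNA-gene variant not written with DNA letters (T instead of U)
descending_range	error	residue range with start greater than end
overlapping_edits	error	edits touching the same reference residues
stop_not_last	error	stop codon '*' not the final replacement residue
ambiguous_locus	warning	bare gene symbol before '::' does not say whether the locus allele is wild type
truncation_name	warning	truncation short name ending in (Delta)N/(Delta)C-style suffix
period_separator	warning	legacy period used where a hyphen is recommended
superscript	warning	superscript characters cannot be stored; flattened to plain text
species_prefix	warning	symbol may embed a species reference
unknown_gene	warning	gene symbol not present in the reference set
deprecated_alias	warning	legacy component name with a recommended replacement
char_normalized	info	Unicode lookalike normalized to its ASCII equivalent
short_name	info	unstructured allele short name (legal; lesion not machine-readable)
unknown_token	info	token not in the feature lexicon
no_reference_length	info	retained-mode deletion kept: reference length unknown
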