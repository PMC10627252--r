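# Published regular expressions for allele gene-variant-feature suffixes
# (characters after the gene symbol), kept verbatim for interoperability
# with the community pattern file. [A-Z*] stands for residue letters plus
# the stop codon; matching restricted to one alphabet (amino acid or DNA)
# is recommended. The package's assembled recognizer (variant_suffix_regex())
# applies that restriction and additionally accepts the comma-separated CTD
# repeat list written out in the guideline text.
name	pattern
wild_type	\+
deletion	Δ
partial_deletion_retained	\(((?<!\d)\d+-\d+,?)+(?<!,)\)
partial_deletion_removed	Δ\(((?<!\d)\d+-\d+,?)+(?<!,)\)
edits	-((?<=[,-])[A-Z]+\d+[A-Z*]+,?)+(?<!,)
ctd	(Δ\(((?<!\d)\d+-\d+,?)+(?<!,)\)|\(((?<!\d)\d+-\d+,?)+(?<!,)\)|-((?<=[,-])[A-Z]+\d+[A-Z*]+,?)+(?<!,))?-CTD-((?<=[,-])(Δ\(((?<!\d)\d+-\d+,?)+(?<!,)\)|([A-Z]+\d+[A-Z*]+)|Δ)(\(r\d+-r\d+(-\d+)?\))?,?)+(?<!,)
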