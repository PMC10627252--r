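# Historical gene-symbol exceptions: community symbols that predate or are
# exempt from the three-letters-plus-digits rule. Editable; one symbol per row.
symbol	note
mrpl1	mitochondrial ribosomal protein, 4-letter prefix shared with budding yeast
mrpl66	mitochondrial ribosomal protein, 4-letter prefix shared with budding yeast
rpl35A01	cytoplasmic ribosomal protein, resolves rpl35/rpl35A conflict
rpl35A02	cytoplasmic ribosomal protein, resolves rpl35/rpl35A conflict
pabp	poly(A)-binding protein, avoids confusion with pab1 phosphatase
cox1-I1b	intronic cox1 protein-coding transcript
cox1-I2b	intronic cox1 protein-coding transcript
mat1-Mc	mating type locus gene
mat1-Mi	mating type locus gene
mat1-Pc	mating type locus gene
mat1-Pi	mating type locus gene
snR51b	nucleolar RNA
snoR02	nucleolar RNA
snoU14	nucleolar RNA
snoZ	nucleolar RNA
snoZ16	nucleolar RNA
rnpB	previously published noncoding RNA
IRC1-L	previously published noncoding RNA
nc-pho1	previously published noncoding RNA
nc-tco1	previously published noncoding RNA
nc-tgp1	previously published noncoding RNA
cti6-antisense-1	previously published noncoding RNA
lncRNA584	previously published noncoding RNA
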