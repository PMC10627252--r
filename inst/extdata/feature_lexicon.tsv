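# Known nonvariant-feature tokens used inside allele names, with the FlyBase
# relationship category each maps to. Users may extend this table.
# categories: tag, regulatory, marker, recombination_site, encoded_tool, carried, linker
token	category	note
GFP	tag	green fluorescent protein
meGFP	tag	monomeric enhanced GFP
sfGFP	tag	superfolder GFP
CFP	tag	cyan fluorescent protein
YFP	tag	yellow fluorescent protein
mCherry	tag	red fluorescent protein
mNeonGreen	tag	green fluorescent protein
tdTomato	tag	red fluorescent protein
GST	tag	glutathione S-transferase purification tag
HA	tag	hemagglutinin epitope tag
FLAG	tag	FLAG epitope tag
Myc	tag	Myc epitope tag
TAP	tag	tandem affinity purification tag
His6	tag	hexahistidine tag
NLS	tag	nuclear localization signal
NES	tag	nuclear export signal
AID	tag	auxin-inducible degron tag
IAA17	tag	auxin-inducible degron tag
kanMX6	marker	G418/kanamycin resistance cassette
natMX6	marker	nourseothricin resistance cassette
hphMX6	marker	hygromycin B resistance cassette
bleMX6	marker	phleomycin resistance cassette
kanMX4	marker	G418/kanamycin resistance cassette
LEU2	marker	budding-yeast leucine marker
URA3	marker	budding-yeast uracil marker
loxP	recombination_site	Cre recombination site
lox71	recombination_site	Cre recombination site
lox66	recombination_site	Cre recombination site
FRT	recombination_site	FLP recombination site
attB	recombination_site	phiC31 recombination site
attP	recombination_site	phiC31 recombination site
P3nmt1	regulatory	full-strength nmt1 promoter (pREP3)
P41nmt1	regulatory	attenuated nmt1 promoter (pREP41)
P81nmt1	regulatory	weakest nmt1 promoter (pREP81)
Padh1	regulatory	adh1 promoter
Purg1	regulatory	urg1 promoter
TIR1	encoded_tool	auxin receptor F-box adaptor
Lifeact	encoded_tool	actin-binding peptide reporter
Cre	encoded_tool	Cre recombinase
Cas9	encoded_tool	Cas9 nuclease
lacZ	encoded_tool	beta-galactosidase reporter
linker	linker	unspecified linker sequence
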