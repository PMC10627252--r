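# Legacy token patterns and their recommended replacements.
# legacy_pattern is a regular expression anchored by the harmonizer.
# categories: promoter, marker, separator, unicode
legacy_pattern	recommended	category
P3-nmt1	P3nmt1	promoter
P3Xnmt1	P3nmt1	promoter
P3xnmt1	P3nmt1	promoter
Pnmt1	P3nmt1	promoter
pnmt1	P3nmt1	promoter
nmt1p	P3nmt1	promoter
P41-nmt1	P41nmt1	promoter
P41Xnmt1	P41nmt1	promoter
P41xnmt1	P41nmt1	promoter
Pnmt41	P41nmt1	promoter
P81-nmt1	P81nmt1	promoter
P81Xnmt1	P81nmt1	promoter
P81xnmt1	P81nmt1	promoter
Pnmt81	P81nmt1	promoter
kan[rR]	kanMX6	marker
kanMX	kanMX6	marker
nat[rR]	natMX6	marker
natMX	natMX6	marker
(hyg|hph)[rR]	hphMX6	marker
hphMX	hphMX6	marker
(ble|phleo)[rR]	bleMX6	marker
bleMX	bleMX6	marker
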