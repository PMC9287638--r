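# synthetic example interaction dump (extended SIF, extra columns ignored)
TP53	interacts-with	GATA3	pc12
GATA3	interacts-with	TP53	pc12
NANOG	controls-expression-of	SOX2	pc12
SOX2	interacts-with	POU5F1	pc12
POU5F1	interacts-with	KLF4	pc12
TP53	interacts-with	CHEBI:15377	pc12
CHEBI:27732	interacts-with	SOX2	pc12
TP53	interacts-with	TP53	pc12
TP53	interacts-with	EGFR	pc12
ACTB	interacts-with	TP53	pc12
NANOG	interacts-with	SOX2	pc12
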