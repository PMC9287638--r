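GENE PRODUCT DB	GENE PRODUCT ID	SYMBOL	QUALIFIER	GO TERM	GO ASPECT	TAXON ID
UniProtKB	P04637	TP53	involved_in	GO:0030154	P	9606
UniProtKB	P04637	Tp53	involved_in	GO:0030154	P	9606
UniProtKB	P23771	GATA3	involved_in	GO:0030154	P	9606
UniProtKB	Q9H9S0	NANOG	involved_in	GO:0030154	P	9606
UniProtKB	P48431	SOX2	involved_in	GO:0030154	P	9606
UniProtKB	Q01860	POU5F1	involved_in	GO:0030154	P	9606
UniProtKB	O43474	KLF4	involved_in	GO:0048468	P	9606
UniProtKB	P60710	ACTB	involved_in	GO:0030154	P	10090
UniProtKB	P00533	EGFR	involved_in	GO:0007165	P	9606
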