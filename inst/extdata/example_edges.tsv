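from	to
GATA3	TP53
NANOG	SOX2
POU5F1	SOX2
KLF4	POU5F1
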