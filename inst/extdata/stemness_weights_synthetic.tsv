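set	gene	weight
stemness_synthetic	SOX2	0.92
stemness_synthetic	POU5F1	0.88
stemness_synthetic	NANOG	0.85
stemness_synthetic	LIN28A	0.71
stemness_synthetic	DNMT3B	0.64
stemness_synthetic	TERT	0.52
stemness_synthetic	MYC	0.47
stemness_synthetic	KLF4	0.33
stemness_synthetic	CD24	0.21
stemness_synthetic	EPCAM	0.18
stemness_synthetic	GATA6	-0.24
stemness_synthetic	SOX17	-0.31
stemness_synthetic	FOXA2	-0.42
stemness_synthetic	CDX2	-0.55
stemness_synthetic	HAND1	-0.63
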