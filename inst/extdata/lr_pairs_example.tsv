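ligand	receptor	subunits	source
TNFSF13B	TNFRSF13B		example
TNFSF13B	TNFRSF17		example
APRIL	TNFRSF13B		example
IL6	IL6R	IL6R,IL6ST	example
CCL5	CCR5		example
CCL3	CCR1		example
CXCL12	CXCR4		example
VEGFA	FLT1		example
IGF1	IGF1R		example
TNF	TNFRSF1A		example
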