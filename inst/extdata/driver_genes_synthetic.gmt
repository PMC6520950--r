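aml	synthetic driver list	TP53	FLT3	NPM1	DNMT3A	IDH1	IDH2	TET2	RUNX1	CEBPA	KIT	NRAS	KRAS	WT1	PCS005
breast	synthetic driver list	TP53	PIK3CA	GATA3	CDH1	MAP3K1	PTEN	AKT1	ESR1	ERBB2	FOXA1	SF3B1	CBFB	RB1	NF1	ARID1A	KMT2C
stomach	synthetic driver list	TP53	ARID1A	PIK3CA	CDH1	RHOA	SMAD4	APC	KRAS	ERBB2	CTNNB1	MUC6	RNF43
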