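mapk_cascade	synthetic example set	EGFR|1	KRAS|1	BRAF|1	MAP2K1|1	MAPK1|1	MAPK3|1	DUSP6|-0.5	SPRY2|-0.5	FOS|1	JUN|1	MYC|1	ELK1|1
cell_cycle_arrest	synthetic example set	CDKN1A|1	CDKN1B|1	TP53|1	RB1|1	CCND1|-1	CCNE1|-1	CDK4|-1	CDK6|-1	E2F1|-1	MDM2|-0.5	GADD45A|1	BTG2|1
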