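mir150_targets_synthetic	synthetic stand-in for a predicted miR-150 target list	TP53	CTNNB1	HMGA2	PIK3CB	CCND2	GSK3B	CDKN1B	AKT1	PTEN	MMP2	MMP9	CASP3	MKI67	COL1A1	COL3A1	CTGF	FN1	TGFB1	CCND1	E2F1
leiomyoma_genes_synthetic	synthetic stand-in for a curated leiomyoma gene list	TP53	CTNNB1	HMGA2	PIK3CB	CCND2	GSK3B	CDKN1B	ESR1	PGR	MED12	FH	COL4A5
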