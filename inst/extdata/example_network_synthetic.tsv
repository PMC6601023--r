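node1	node2	combined_score
TP53	CTNNB1	920
TP53	CCND2	780
TP53	CDKN1B	850
CTNNB1	GSK3B	990
CTNNB1	HMGA2	710
GSK3B	AKT1	940
AKT1	CDKN1B	900
AKT1	PTEN	970
AKT1	PIK3CB	950
PIK3CB	PTEN	930
CDKN1B	CCND2	820
CCND1	CDKN1B	880
TP53	MMP9	640
HMGA2	E2F1	560
FN1	CTGF	750
COL1A1	COL3A1	810
TGFB1	CTGF	860
TGFB1	COL1A1	720
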