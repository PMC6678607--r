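CD8_ACTIVATED	activated CD8 T-cell program (package default)	CD8A	CD8B	GZMA	GZMB	GZMK	PRF1	IFNG	NKG7	KLRG1	CST7	CCL4	CTSW	EOMES	ZAP70	CD3D	CD3E
ESTIMATE_IMMUNE	immune-infiltrate marker panel (package default)	PTPRC	CD2	CD3D	CD3E	CD48	CD52	CD53	LCP2	IL7R	CXCR4	LTB	SELL	CCL19	CCR7	ITGAL	TRBC1	IKZF1	CD27	KLRB1	CD69
ESTIMATE_STROMAL	stromal marker panel (package default)	COL1A1	COL1A2	COL3A1	COL5A1	FAP	FN1	PDGFRA	PDGFRB	THBS2	DCN	LUM	POSTN	ACTA2	TAGLN	SPARC	VCAN	MMP2	FBLN1	CDH11	ZEB1
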