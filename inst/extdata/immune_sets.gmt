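PRIMARY_IMMUNODEFICIENCY	KEGG-style primary immunodeficiency gene set	AIRE	CD40LG	IGLL1	RAG1	TAP1	TNFRSF13B	CD19	BTK	ADA	JAK3	IL2RG	RAG2	ICOS	CD81
JAK_STAT_SIGNALING	JAK-STAT signaling pathway members	STAT5B	PIK3R1	PIK3CD	STAT3	STAT1	JAK3	IL21R	IL10RA	IL10RB	IL2RG	EPOR	GHR
T_CELL_RECEPTOR_SIGNALING	T-cell receptor signaling pathway members	CD40LG	CTLA4	NFKB1	PIK3R1	PIK3CD	CD8A	LCK	ZAP70	LAT
TOLL_LIKE_RECEPTOR_SIGNALING	Toll-like receptor signaling pathway members	NFKB1	PIK3CD	TBK1	TIRAP	TLR4	MYD88	IRF3
NON_IMMUNE_CONTROL	Housekeeping control set with no expected overlap	ACTB	GAPDH	MYH7	TTN	COL1A1	ALB	APOE
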