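# CVID/PID gene panel: 13 OMIM-curated CVID genes tagged CVID_OMIM,
# remaining primary-immunodeficiency genes tagged PID.
LRBA	CVID_OMIM
RAG1	CVID_OMIM
CD40LG	CVID_OMIM
CTLA4	CVID_OMIM
NFKB1	CVID_OMIM
IL21R	CVID_OMIM
TNFRSF13B	CVID_OMIM
ICOS	CVID_OMIM
CD19	CVID_OMIM
CD81	CVID_OMIM
MS4A1	CVID_OMIM
TNFRSF13C	CVID_OMIM
NFKB2	CVID_OMIM
AIRE	PID
TNFSF11	PID
PSTPIP1	PID
CD8A	PID
PIK3R1	PID
PIK3CD	PID
MYSM1	PID
IL17RA	PID
TAP1	PID
IL10RA	PID
TIRAP	PID
TBK1	PID
IGLL1	PID
IL10RB	PID
GATA2	PID
TFRC	PID
KMT2D	PID
STAT5B	PID
NCF2	PID
TCIRG1	PID
BTK	PID
DOCK8	PID
WAS	PID
STAT3	PID
STAT1	PID
JAK3	PID
IL2RG	PID
ADA	PID
RAG2	PID
FOXP3	PID
CD40	PID
AICDA	PID
UNG	PID
IKBKG	PID
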