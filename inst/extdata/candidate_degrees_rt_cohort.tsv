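gene_id	comparison	degree	synthetic
ATIC	ATRT_vs_KRT	5	0
ATIC	ATRT_vs_brain	6	0
ATIC	KRT_vs_kidney	1	0
DDB2	ATRT_vs_KRT	1	0
DDB2	ATRT_vs_brain	2	0
DDB2	KRT_vs_kidney	3	0
FANCA	ATRT_vs_KRT	7	0
FANCA	ATRT_vs_brain	1	0
FANCA	KRT_vs_kidney	1	0
GNAS	ATRT_vs_KRT	2	0
GNAS	ATRT_vs_brain	13	0
GNAS	KRT_vs_kidney	7	0
NONO	ATRT_vs_KRT	7	0
NONO	ATRT_vs_brain	19	0
NONO	KRT_vs_kidney	7	0
NPM1	ATRT_vs_KRT	11	0
NPM1	ATRT_vs_brain	3	0
NPM1	KRT_vs_kidney	10	0
PBRM1	ATRT_vs_KRT	6	0
PBRM1	ATRT_vs_brain	21	0
PBRM1	KRT_vs_kidney	8	0
PCM1	ATRT_vs_KRT	8	0
PCM1	ATRT_vs_brain	6	0
PCM1	KRT_vs_kidney	13	0
PDE4DIP	ATRT_vs_KRT	9	0
PDE4DIP	ATRT_vs_brain	11	0
PDE4DIP	KRT_vs_kidney	3	0
PTEN	ATRT_vs_KRT	13	0
PTEN	ATRT_vs_brain	15	0
PTEN	KRT_vs_kidney	11	0
RPL10	ATRT_vs_KRT	7	0
RPL10	ATRT_vs_brain	9	0
RPL10	KRT_vs_kidney	11	0
RPL22	ATRT_vs_KRT	4	0
RPL22	ATRT_vs_brain	4	0
RPL22	KRT_vs_kidney	12	0
RPL5	ATRT_vs_KRT	8	0
RPL5	ATRT_vs_brain	6	0
RPL5	KRT_vs_kidney	14	0
SF3B1	ATRT_vs_KRT	13	0
SF3B1	ATRT_vs_brain	26	0
SF3B1	KRT_vs_kidney	12	0
SMARCE1	ATRT_vs_KRT	5	0
SMARCE1	ATRT_vs_brain	3	0
SMARCE1	KRT_vs_kidney	1	0
SRSF3	ATRT_vs_KRT	6	0
SRSF3	ATRT_vs_brain	2	0
SRSF3	KRT_vs_kidney	5	0
SUZ12	ATRT_vs_KRT	5	0
SUZ12	ATRT_vs_brain	21	0
SUZ12	KRT_vs_kidney	2	0
TCF3	ATRT_vs_KRT	8	0
TCF3	ATRT_vs_brain	2	0
TCF3	KRT_vs_kidney	7	0
ZMYM2	ATRT_vs_KRT	6	1
ZMYM2	ATRT_vs_brain	26	0
ZMYM2	KRT_vs_kidney	12	0
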