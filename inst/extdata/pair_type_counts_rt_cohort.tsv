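comparison	tier	dys_type	n_pairs
ATRT_vs_brain	AllPCG	I	66125
ATRT_vs_brain	AllPCG	II	3059
ATRT_vs_brain	AllPCG	III	16
ATRT_vs_brain	AllPCG	IV	36
ATRT_vs_brain	DiffPCG	I	18651
ATRT_vs_brain	DiffPCG	II	232
ATRT_vs_brain	DiffPCG	III	4
ATRT_vs_brain	DiffPCG	IV	2
ATRT_vs_brain	CancerG	I	2629
ATRT_vs_brain	CancerG	II	138
ATRT_vs_brain	CancerG	III	2
ATRT_vs_brain	CancerG	IV	4
KRT_vs_kidney	AllPCG	I	16408
KRT_vs_kidney	AllPCG	II	28350
KRT_vs_kidney	AllPCG	III	260
KRT_vs_kidney	AllPCG	IV	157
KRT_vs_kidney	DiffPCG	I	6259
KRT_vs_kidney	DiffPCG	II	7371
KRT_vs_kidney	DiffPCG	III	100
KRT_vs_kidney	DiffPCG	IV	35
KRT_vs_kidney	CancerG	I	675
KRT_vs_kidney	CancerG	II	1284
KRT_vs_kidney	CancerG	III	12
KRT_vs_kidney	CancerG	IV	5
ATRT_vs_KRT	AllPCG	I	5543
ATRT_vs_KRT	AllPCG	II	45245
ATRT_vs_KRT	AllPCG	III	53
ATRT_vs_KRT	AllPCG	IV	21
ATRT_vs_KRT	DiffPCG	I	776
ATRT_vs_KRT	DiffPCG	II	6908
ATRT_vs_KRT	DiffPCG	III	2
ATRT_vs_KRT	DiffPCG	IV	3
ATRT_vs_KRT	CancerG	I	263
ATRT_vs_KRT	CancerG	II	1742
ATRT_vs_KRT	CancerG	III	5
ATRT_vs_KRT	CancerG	IV	1
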