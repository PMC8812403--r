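method	gene	coexpressed_tlrs	common_neighbors	tlrs_in_cluster	total
pearson	BCL6	4	4	4	12
pearson	CCL5	5	6	0	11
pearson	FOXP3	3	4	0	7
pearson	GATA3	3	4	0	7
pearson	CD28	2	4	0	6
pearson	T-bet	3	3	0	6
pearson	NR4A1	3	2	1	6
pearson	CD3	1	3	0	4
pearson	CD40	0	0	4	4
pearson	TIGIT	0	3	1	4
pearson	TCR	0	3	0	3
pearson	CD40L	0	3	0	3
pearson	CTLA4	0	2	0	2
pearson	PD-1	1	0	1	2
pearson	PD-L2	0	2	0	2
pearson	TIM3	0	1	1	2
pearson	CD83	0	1	0	1
pearson	IkBa	0	1	0	1
pearson	p50	0	1	0	1
pearson	RORC	0	1	0	1
pearson	LAG3	0	0	1	1
pearson	TNF	0	1	0	1
pearson	p65	0	0	0	0
pearson	PD-L1	0	0	0	0
spearman	BCL6	4	8	4	16
spearman	TIGIT	4	6	4	14
spearman	IkBa	4	5	4	13
spearman	NR4A1	2	6	4	12
spearman	FOXP3	3	8	0	11
spearman	CCL5	5	5	0	10
spearman	CD28	3	6	0	9
spearman	GATA3	3	4	0	7
spearman	T-bet	3	2	0	5
spearman	TCR	1	4	0	5
spearman	CD40L	0	5	0	5
spearman	CD83	1	3	0	4
spearman	PD-L2	0	3	1	4
spearman	LAG3	0	0	4	4
spearman	TNF	1	3	0	4
spearman	CD3	0	2	0	2
spearman	p50	0	2	0	2
spearman	CD40	0	1	0	1
spearman	CTLA4	0	1	0	1
spearman	PD-L1	0	1	0	1
spearman	p65	0	0	0	0
spearman	PD-1	0	0	0	0
spearman	RORC	0	0	0	0
spearman	TIM3	0	0	0	0
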