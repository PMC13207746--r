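dataset_id	pmid	condition_code	gene	accession	residue	position	fold_change	p_value
D01	30000001	EGF_10min	CAV1	Q03135	Y	14	2.0	0.01
D01	30000001	EGF_10min	SRC	P12931	S	17	1.8	0.02
D02	30000001	EGF_60min	CAV1	Q03135	Y	14	0.5	0.01
D02	30000001	EGF_60min	SRC	P12931	S	17	0.6	0.03
D03	30000002	HYPOXIA	VIP21	Q03135	Y	14	1.5	0.2
D03	30000002	HYPOXIA	CAV1	Q03135	S	37	1.4	0.04
D03	30000002	HYPOXIA	UNKNOWNX	X00000	S	5	1.5	0.01
D04	30000003	OSMOTIC	CAV1	Q03135	Y	14	1.31	0.04
D04	30000003	OSMOTIC	CAV1	Q03135	S	37	0.7	0.02
D04	30000003	OSMOTIC	SRC	P12931	S	17	1.35	0.2
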