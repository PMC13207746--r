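dataset_id	pmid	condition_code	gene	accession	residue	position	loc_prob	ascore
P01	30000001	EGF_10min	CAV1	Q03135	Y	14	0.99	
P01	30000001	EGF_10min	VIP21	Q03135	S	37	0.88	
P01	30000001	EGF_10min	CAV1	Q03135	S	37		20
P02	30000001	EGF_60min	CAV1	Q03135	Y	14		14
P02	30000001	EGF_60min	CAV1	Q03135	S	37	0.80	
P03	30000002	HYPOXIA	CAV1	Q03135	Y	14	0.76	
P03	30000002	HYPOXIA	SRC	P12931	Y	419	0.95	
P04	30000003	OSMOTIC	CAV1	Q03135	S	37	0.74	13
P04	30000003	OSMOTIC	CAV1	Q03135	Y	14	0.75	
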