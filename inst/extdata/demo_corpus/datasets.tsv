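dataset_id	pmid	condition_code	dataset_type	enrichment
P01	30000001	EGF_10min	profiling	STY
P02	30000001	EGF_60min	profiling	STY
P03	30000002	HYPOXIA	profiling	Y
P04	30000003	OSMOTIC	profiling	ST
D01	30000001	EGF_10min	differential	STY
D02	30000001	EGF_60min	differential	STY
D03	30000002	HYPOXIA	differential	Y
D04	30000003	OSMOTIC	differential	ST
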