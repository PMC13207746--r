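alias	symbol
CAV1	CAV1
VIP21	CAV1
SRC	SRC
CAVIN1	CAVIN1
PTRF	CAVIN1
ERBB2	ERBB2
ERBB3	ERBB3
MET	MET
EPHA2	EPHA2
LYN	LYN
TEC	TEC
ABL2	ABL2
VCL	VCL
SNAP23	SNAP23
CSNK1E	CSNK1E
GRK5	GRK5
FLOT1	FLOT1
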