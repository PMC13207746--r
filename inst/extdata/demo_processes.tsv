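gene	residue	position	process
SRC	S	17	carcinogenesis
MET	Y	1234	carcinogenesis
ERBB2	Y	877	carcinogenesis
EPHA2	Y	772	cell_migration
CAVIN1	Y	308	membrane_organization
LYN	Y	32	immune_signaling
VCL	S	272	cell_adhesion
SNAP23	S	110	vesicular_trafficking
CSNK1E	S	389	signaling_regulation
GRK5	S	484	signaling_regulation
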