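kinase	substrate_gene	residue	position	evidence	source
SRC	CAV1	Y	14	validated	PhosphoSitePlus_demo
ABL2	CAV1	Y	14	predicted	SyntheticPeptideAtlas_demo
ERBB2	CAV1	Y	14	predicted	NetworKIN_demo
ERBB3	CAV1	Y	14	predicted	NetworKIN_demo
LYN	CAV1	Y	14	predicted	AKID_demo
TEC	CAV1	Y	14	predicted	iKiP-DB_demo
CSNK1E	CAV1	S	37	predicted	NetworKIN_demo
GRK5	CAV1	S	37	predicted	AKID_demo
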