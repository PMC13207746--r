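partner	source_db
CAVIN1	HPRD
CAVIN1	BioGRID
CAVIN1	CORUM
EPHA2	BioGRID
EPHA2	ConsensusPathDB
ERBB2	HPRD
ERBB2	BioGRID
MET	BioGRID
MET	ConsensusPathDB
SRC	HPRD
SRC	BioGRID
SRC	CORUM
VCL	BioGRID
VCL	CORUM
FLOT1	BioGRID
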