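symbol	accession
CAV1	Q03135
SRC	P12931
CAVIN1	Q6NZI2
ERBB2	P04626
ERBB3	P21860
MET	P08581
EPHA2	P29317
LYN	P07948
TEC	P42680
ABL2	P42684
VCL	P18206
SNAP23	O00161
CSNK1E	P49674
GRK5	P34947
FLOT1	O75955
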