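resname	formal_charge	sidechain_reach
ALA	0	0.00
ARG	1	5.14
ASN	0	2.47
ASP	-1	2.47
CYS	0	1.81
GLN	0	3.75
GLU	-1	3.74
GLY	0	0.00
HIS	1	3.65
ILE	0	0.00
LEU	0	0.00
LYS	1	4.95
MET	0	2.73
PHE	0	0.00
PRO	0	0.00
SER	0	1.43
THR	0	1.43
TRP	0	3.68
TYR	0	5.63
VAL	0	0.00
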