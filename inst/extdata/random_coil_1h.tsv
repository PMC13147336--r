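resname	nucleus	shift
ALA	HA	4.32
ARG	HA	4.34
ASN	HA	4.74
ASP	HA	4.64
CYS	HA	4.71
GLN	HA	4.34
GLU	HA	4.35
GLY	HA	3.96
HIS	HA	4.60
ILE	HA	4.17
LEU	HA	4.34
LYS	HA	4.32
MET	HA	4.48
PHE	HA	4.62
PRO	HA	4.42
SER	HA	4.47
THR	HA	4.35
TRP	HA	4.66
TYR	HA	4.55
VAL	HA	4.12
AIB	MB	1.42
DAB	HA	4.35
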