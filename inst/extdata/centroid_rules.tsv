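het_code	equivalent_code	centroid_atom	category
CSE	CYS	CA	nonstandard
SEC	CYS	CA	nonstandard
MSE	MET	CA	nonstandard
PTR	TYR	CA	nonstandard
SEP	SER	CA	nonstandard
TPO	THR	CA	nonstandard
KCX	LYS	CA	nonstandard
LLP	LYS	CA	nonstandard
HYP	PRO	CA	nonstandard
HEM	HEM	FE	cofactor
HEC	HEC	FE	cofactor
HEA	HEA	FE	cofactor
FAD	FAD	N5	cofactor
FMN	FMN	N5	cofactor
MGD	MGD	S13	cofactor
PLP	PLP	C4A	cofactor
NAD	NAD	C4N	cofactor
SAM	SAM	SD	cofactor
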