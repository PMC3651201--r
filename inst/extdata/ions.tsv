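ion_code
ZN
MG
MN
FE
FE2
CA
NA
K
CU
CU1
NI
CO
CD
HG
MO
W
SR
BA
CS
LI
AL
PB
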