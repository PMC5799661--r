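name	consensus	both_strands
G-box	CACGTG	TRUE
E-box	CANNTG	TRUE
ABRE	ACGTG	TRUE
MBS	CAACTG	TRUE
MRE	AACCTAA	TRUE
HSE	AAAAAATTTC	TRUE
LTR	CCGAAA	TRUE
CRT/DRE	RCCGAC	TRUE
P-box	CCTTTTG	TRUE
TATC-box	TATCCCA	TRUE
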