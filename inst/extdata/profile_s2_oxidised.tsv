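label	energy_kjmol	note
RS_2	0	second-half-reaction reactive state before the one-electron reduction
TS1_2	18	C5'-S_A cleavage transition state without prior reduction; printed 18 kJ/mol barrier
IM1_2ox	-62	cleavage product without prior reduction; printed 62 kJ/mol exothermicity
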