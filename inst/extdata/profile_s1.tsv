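label	energy_kjmol	note
RS_1	0	reactive state of the first S-insertion half-reaction; profile reference
TS1_1	6	C5'-S_A cleavage transition state; height is the printed 6 kJ/mol barrier above RS_1
IM_1	-42	radical intermediate after C5'-S_A cleavage; printed 42 kJ/mol exothermicity below RS_1
TS2_1	-5	H6-abstraction transition state; printed 37 kJ/mol barrier above IM_1
PS_1	-184	first-insertion product with the C6-S6 bond formed; printed 184 kJ/mol below RS_1
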