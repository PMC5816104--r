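label	energy_kjmol	note
RS_2	0	reduced reactive state of the second S-insertion half-reaction; profile reference
IM1_2	-101	barrierless C5'-S_A cleavage product; printed 101 kJ/mol below the reduced RS_2
TS2_2	-30	H8-abstraction transition state; printed 71 kJ/mol barrier above IM1_2
IM2_2	-125	C8-radical intermediate; printed 24 kJ/mol below IM1_2
IM2_2p	-105	rotated C8-radical conformer; printed 20 kJ/mol above IM2_2
TS3_2	-63	S1 attack on the C8 radical (mechanism 1); printed 42 kJ/mol barrier above IM2_2p
PS2_2	-69	mechanism-1 product; printed at -69 kJ/mol on the half-reaction scale
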