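label	energy_kjmol	note
RS_2	0	reduced reactive state of the second S-insertion half-reaction; profile reference
IM1_2	-101	barrierless C5'-S_A cleavage product; printed 101 kJ/mol below the reduced RS_2
TS2_2	-30	H8-abstraction transition state; printed 71 kJ/mol barrier above IM1_2
IM2_2	-125	C8-radical intermediate; printed 24 kJ/mol below IM1_2
IM2_2p	-105	rotated C8-radical conformer; printed 20 kJ/mol above IM2_2
TS3_2p	-71	S3 attack on the C8 radical (mechanism 2); printed 34 kJ/mol barrier above IM2_2p; a concluding summary also quotes 30 kJ/mol for this step with an unstated reference state
PS2_2p	-95	mechanism-2 product; printed at -95 kJ/mol on the half-reaction scale
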