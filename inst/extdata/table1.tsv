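label	family	column	energy_kjmol	provenance
[↑↓↑↓ ↓↑↓↑]	main_fixed	resting	0	reference state of the published spin-state survey, resting column
[↑↓↑↓ ↓↑↓↑]	main_fixed	reactive	0	reference state of the published spin-state survey, reactive column
[↑↓↑↓ ↑↓↓↑]	main_fixed	resting	-4.7	published survey, main cluster fixed, resting column
[↑↓↑↓ ↑↓↓↑]	main_fixed	reactive	23.7	published survey, main cluster fixed, reactive column
[↑↓↑↓ ↑↑↓↓]	main_fixed	resting	2.7	published survey, main cluster fixed, resting column
[↑↓↑↓ ↑↑↓↓]	main_fixed	reactive	37.4	published survey, main cluster fixed, reactive column
[↑↓↑↓ ↓↓↑↑]	main_fixed	resting	1.9	published survey, main cluster fixed, resting column
[↑↓↑↓ ↓↓↑↑]	main_fixed	reactive	0.4	published survey, main cluster fixed, reactive column
[↑↓↑↓ ↓↑↑↓]	main_fixed	resting	-5.9	published survey, main cluster fixed, resting column; also matches the fixed auxiliary pattern
[↑↓↑↓ ↓↑↑↓]	main_fixed	reactive	-2.1	published survey, main cluster fixed, reactive column; also matches the fixed auxiliary pattern
[↑↓↑↓ ↑↓↑↓]	main_fixed	resting	-0.9	published survey, main cluster fixed, resting column
[↑↓↑↓ ↑↓↑↓]	main_fixed	reactive	21.2	published survey, main cluster fixed, reactive column
[↓↑↑↓ ↓↑↑↓]	aux_fixed	resting	-19.3	published survey, auxiliary cluster fixed, resting column
[↓↑↑↓ ↓↑↑↓]	aux_fixed	reactive	1.8	published survey, auxiliary cluster fixed, reactive column
[↓↓↑↑ ↓↑↑↓]	aux_fixed	resting	-18.9	published survey, auxiliary cluster fixed, resting column
[↓↓↑↑ ↓↑↑↓]	aux_fixed	reactive	NA	determinant did not converge in the published survey (dash in the source table)
[↑↑↓↓ ↓↑↑↓]	aux_fixed	resting	-17.7	published survey, auxiliary cluster fixed, resting column
[↑↑↓↓ ↓↑↑↓]	aux_fixed	reactive	-9.1	published survey, auxiliary cluster fixed, reactive column; survey ground state
[↑↓↓↑ ↓↑↑↓]	aux_fixed	resting	-14.4	published survey, auxiliary cluster fixed, resting column
[↑↓↓↑ ↓↑↑↓]	aux_fixed	reactive	0.7	published survey, auxiliary cluster fixed, reactive column
[↓↑↓↑ ↓↑↑↓]	aux_fixed	resting	-7.6	published survey, auxiliary cluster fixed, resting column
[↓↑↓↑ ↓↑↑↓]	aux_fixed	reactive	5.1	published survey, auxiliary cluster fixed, reactive column
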