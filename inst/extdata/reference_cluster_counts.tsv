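condition	band	n_ers	n_erd
CLs	Alpha	2	8
CLs	Beta	0	13
CLs	LowG	0	2
CLs	MidG	29	1
CLs	HigG	11	1
CLsm	Alpha	3	1
CLsm	Beta	1	5
CLsm	LowG	1	1
CLsm	MidG	14	1
CLsm	HigG	7	0
ILs	Alpha	4	2
ILs	Beta	3	2
ILs	LowG	3	1
ILs	MidG	4	3
ILs	HigG	10	2
ILsm	Alpha	4	1
ILsm	Beta	1	1
ILsm	LowG	1	2
ILsm	MidG	2	2
ILsm	HigG	1	1
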