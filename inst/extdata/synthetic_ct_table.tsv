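sample	amplicon	ct	replicate
dKD	18S	12.1	1
dKD	18S	12.0	2
dKD	18S	11.9	3
dKD	COX3_pre	22.0	1
dKD	COX3_pre	22.1	2
dKD	COX3_pre	21.9	3
dKD	COX3_ed	26.6	1
dKD	COX3_ed	26.4	2
dKD	COX3_ed	26.5	3
dKD	CYB_pre	24.0	1
dKD	CYB_pre	24.1	2
dKD	CYB_pre	23.9	3
dKD	CYB_ed	27.1	1
dKD	CYB_ed	26.9	2
dKD	CYB_ed	27.0	3
dKD	ND4	21.6	1
dKD	ND4	21.8	2
dKD	ND4	21.7	3
ATM1	18S	12.0	1
ATM1	18S	12.1	2
ATM1	18S	11.9	3
ATM1	COX3_pre	23.5	1
ATM1	COX3_pre	23.4	2
ATM1	COX3_pre	23.6	3
ATM1	COX3_ed	24.5	1
ATM1	COX3_ed	24.6	2
ATM1	COX3_ed	24.4	3
ATM1	CYB_pre	25.0	1
ATM1	CYB_pre	24.9	2
ATM1	CYB_pre	25.1	3
ATM1	CYB_ed	25.8	1
ATM1	CYB_ed	25.9	2
ATM1	CYB_ed	25.7	3
ATM1	ND4	22.3	1
ATM1	ND4	22.2	2
ATM1	ND4	22.4	3
IP	ND4	19.0	1
IP	ND4	19.1	2
IP	RPS12_pre	20.5	1
IP	RPS12_pre	20.4	2
IP	COX3_pre	21.0	1
IP	COX3_pre	21.1	2
Input	ND4	20.0	1
Input	ND4	20.1	2
Input	RPS12_pre	19.8	1
Input	RPS12_pre	19.9	2
Input	COX3_pre	20.6	1
Input	COX3_pre	20.5	2
MockIP	ND4	25.5	1
MockIP	ND4	25.6	2
MockIP	RPS12_pre	26.8	1
MockIP	RPS12_pre	26.7	2
MockIP	COX3_pre	27.2	1
MockIP	COX3_pre	27.3	2
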