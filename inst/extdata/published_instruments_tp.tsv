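SNP	CHR	POS	BETA_X	P_X	BETA_Y	P_Y
chr02_21604477	2	21604477	-1.279	8.25e-07	-1.977	0.043
chr06_1578700	6	1578700	-0.639	4.52e-07	-1.691	3.21e-04
chr11_26492375	11	26492375	-0.507	7.04e-08	-0.720	0.043
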