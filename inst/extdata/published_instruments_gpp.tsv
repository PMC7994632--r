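SNP	CHR	POS	BETA_X	P_X	BETA_Y	P_Y
chr03_29979498	3	29979498	-18.724	1.12e-07	-0.633	0.543
chr03_898774	3	898774	18.953	2.92e-07	1.254	0.299
chr05_7226049	5	7226049	-7.242	2.25e-08	-1.329	0.005
chr08_25257522	8	25257522	-16.559	8.58e-07	1.178	0.553
chr09_12464309	9	12464309	-7.538	4.49e-07	-0.974	0.066
chr12_22633431	12	22633431	15.738	3.01e-07	1.439	0.158
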