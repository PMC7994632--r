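SNP	CHR	POS	BETA_X	P_X	BETA_Y	P_Y
chr01_3547491	1	3547491	0.706	7.14e-08	-0.036	0.948
chr01_5524333	1	5524333	1.018	6.56e-07	0.310	0.840
chr02_1118809	2	1118809	0.786	1.56e-09	1.030	0.082
chr02_334316	2	334316	-1.474	2.38e-07	0.948	0.505
chr02_7792121	2	7792121	-1.256	9.21e-08	0.029	0.980
chr03_17810847	3	17810847	0.651	4.74e-07	0.711	0.394
chr03_33060865	3	33060865	-0.505	2.03e-08	-0.978	0.027
chr04_13785932	4	13785932	0.739	3.16e-07	0.623	0.406
chr05_16393143	5	16393143	0.466	4.71e-07	0.029	0.955
chr07_23215227	7	23215227	0.952	1.09e-07	-0.308	0.715
chr08_25464238	8	25464238	-0.875	2.01e-09	-0.004	0.997
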