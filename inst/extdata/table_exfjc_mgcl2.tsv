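concentration_mM	LK_nm	LK_sd_nm	K_pN	K_sd_pN
0.5	1.59	0.06	710	60
1	1.50	0.03	700	50
2	1.41	0.03	630	60
4	1.41	0.05	670	50
10	1.34	0.04	710	60
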