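concentration_mM	LK_nm	LK_sd_nm	K_pN	K_sd_pN
10	1.91	0.04	760	50
25	1.78	0.06	670	50
50	1.68	0.05	700	50
100	1.55	0.04	630	70
250	1.43	0.06	707	60
500	1.38	0.05	710	50
1000	1.31	0.06	850	100
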