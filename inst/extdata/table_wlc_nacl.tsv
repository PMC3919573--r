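concentration_mM	Lp_nm	Lp_sd_nm	Lc_nm_per_base	Lc_sd_nm_per_base
10	1.19	0.06	0.68	0.02
25	1.04	0.06	0.69	0.02
50	0.99	0.05	0.68	0.02
100	0.87	0.04	0.69	0.03
250	0.81	0.04	0.69	0.03
500	0.78	0.04	0.69	0.02
1000	0.76	0.05	0.70	0.02
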