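concentration_mM	Lp_nm	Lp_sd_nm	Lc_nm_per_base	Lc_sd_nm_per_base
0.5	0.93	0.06	0.69	0.03
1	0.86	0.04	0.69	0.02
2	0.78	0.04	0.70	0.02
4	0.79	0.05	0.70	0.02
10	0.75	0.04	0.70	0.02
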