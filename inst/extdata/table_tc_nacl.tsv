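concentration_mM	delta_nm	delta_sd_nm	l_nm	l_sd_nm	Lc_um	Lc_sd_um
10	0.83	0.03	1.32	0.07	8.48	0.10
25	0.74	0.04	1.21	0.06	8.57	0.10
50	0.71	0.02	1.27	0.03	8.46	0.10
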