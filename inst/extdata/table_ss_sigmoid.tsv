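salt	concentration_mM	fc_pN	delta_pN	x0
NaCl	100	0.440	2.090	0.448
NaCl	250	3.6	1.75	0.313
NaCl	500	4.850	1.637	0.049
NaCl	1000	5.322	1.520	0.029
MgCl2	0.5	0.625	1.958	0.421
MgCl2	1	2.270	2.070	0.250
MgCl2	2	3.310	1.580	0.110
MgCl2	4	4.899	1.610	0.046
MgCl2	10	5.681	1.430	0.018
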