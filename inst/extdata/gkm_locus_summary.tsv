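locus	n_allele	h_obs	h_exp	hwe_significant	null_ch	f_is	null_free
Mu50	10	0.81	0.85	0	0.03	0.063	1
UarT739	7	0.71	0.73	0	0.02	0.046	1
G10X	9	0.76	0.76	0	-0.01	0.009	1
UarD3139	9	0.73	0.82	0	0.06	0.119	1
UarD3684	8	0.67	0.75	0	0.06	0.121	1
G10C	9	0.66	0.83	1	0.12	0.219	0
G1D	8	0.59	0.80	1	0.15	0.278	0
UarD1585	10	0.62	0.86	1	0.16	0.290	0
Mu05	8	0.50	0.69	0	0.16	0.283	0
Mu23	7	0.61	0.80	0	0.14	0.252	0
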