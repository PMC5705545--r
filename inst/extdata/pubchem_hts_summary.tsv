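target_class	said	n_actives	n_inactives
GPCR	435008	233	217925
GPCR	1798	187	61646
GPCR	435034	362	61394
Ion channel	1843	172	301321
Ion channel	2258	213	302192
Ion channel	463087	703	100172
Transporter	488997	252	302054
Kinase inhibitor	2689	172	319620
Enzyme	485290	281	341084
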