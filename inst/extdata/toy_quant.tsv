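accession	wt_1	wt_2	wt_3	wt_4	oe_1	oe_2	oe_3	oe_4	kd_1	kd_2	kd_3	kd_4
P1	1250.5	1300.25	0	1275	2500	2610.75	2498	2550.5	610	0	595.25	601
P2	850	870.5	845	0	860	855	0	849.75	862	858.5	871	0
P3	0	0	450.5	0	0	440	0	0	445.25	0	0	0
P4	3200	3150.75	3180	3220.5	3190	3210	3175.25	3205	3188	3199	3210.5	3179
P5	0	0	0	0	0	0	0	0	0	0	0	0
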