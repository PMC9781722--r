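target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	0	0	1	-1	0	0	-7	-83	-35
10	11	NAN	11	-1	12	0	-1	-74	-36
20	19	NAN	19	-1	19	0	4	-67	-35
30	30	NAN	30	-1	31	0	11	-58	-34
40	38	NAN	38	-1	39	0	16	-49	-32
50	50	NAN	50	-1	52	0	21	-40	-29
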