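target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	16	NAN	17	-1	16	1	2	-69	-35
10	19	10	22	-11	19	1	-4	-61	-35
20	21	18	29	-20	21	1	-10	-54	-35
30	23	31	37	-29	22	1	-18	-47	-36
40	24	39	45	-41	23	1	-25	-40	-38
50	25	49	54	-50	24	2	-32	-32	-41
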