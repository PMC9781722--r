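target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	1	NAN	1	-1	1	0	-6	-82	-36
10	11	3	11	-1	-9	0	-12	-91	-34
20	20	4	20	-1	-20	0	-18	-100	-32
30	29	4	29	-1	-29	0	-23	-108	-29
40	42	5	42	-1	-38	0	-28	-120	-24
50	50	6	50	-1	-51	0	-31	-129	-19
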