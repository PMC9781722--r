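target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	18	NAN	18	-1	18	-1	4	-68	-37
10	22	12	19	-1	19	11	4	-67	-24
20	27	23	17	-1	17	21	3	-69	-15
30	34	28	16	-1	16	30	3	-69	-5
40	42	41	15	-1	15	38	2	-70	4
50	52	51	14	-1	14	52	1	-71	14
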