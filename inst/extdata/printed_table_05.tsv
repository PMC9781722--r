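target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	0	1	1	-1	0	0	-7	-83	-35
10	3	11	11	10	3	0	3	-87	-35
20	2	22	22	21	2	0	11	-93	-36
30	1	29	29	29	1	0	19	-100	-37
40	1	39	39	39	1	1	26	-106	-39
50	2	50	49	48	3	1	34	-113	-43
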