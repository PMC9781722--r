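target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	0	NAN	1	-1	0	0	-2	1	-80
10	10	NAN	10	-1	10	0	7	3	-80
20	21	NAN	21	-1	21	0	18	5	-79
30	31	NAN	31	-1	30	0	27	7	-78
40	40	NAN	40	-1	42	0	36	10	-77
50	51	NAN	51	-1	50	0	46	13	-74
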