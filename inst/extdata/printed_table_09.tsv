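target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	0	NAN	1	-1	0	0	0	5	0
10	11	10	4	-1	-4	-10	0	1	-10
20	21	20	6	-2	-5	-20	0	-1	-20
30	30	30	7	-2	-6	-30	1	-2	-29
40	40	40	8	-3	-8	-39	1	-4	-39
50	51	51	10	-4	-9	-50	0	-6	-50
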