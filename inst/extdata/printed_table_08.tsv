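target	m1_x	m1_y	m1_z	m2_x	m2_y	m2_z	m3_x	m3_y	m3_z
0	17	NAN	17	-2	17	0	3	-68	-35
10	18	9	16	-1	16	-12	2	-70	-46
20	24	22	14	-1	14	-21	1	-71	-56
30	32	31	11	-1	11	-30	-1	-74	-66
40	41	43	9	0	9	-43	-1	-76	-75
50	50	51	8	2	8	-51	-1	-78	-85
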