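target	head_x	head_y	head_z	chest_x	chest_y	chest_z	hips_x	hips_y	hips_z
0	0	0	0	0	0	0	0	0	0
10	10	10	8	11	10	9	10	10	11
20	20	20	19	20	20	20	20	20	18
30	29	30	30	29	30	30	30	30	30
40	40	38	40	40	40	39	40	40	N/A
50	49	50	50	49	50	47	50	49	N/A
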