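class	cell_de	cell_up	cell_down	ev_de	ev_up	ev_down
miRNA	37	26	11	169	99	70
piRNA	6	5	1	77	50	27
tRF	32	25	7	113	92	21
SNORD	44	36	8	91	50	41
SNORA	8	5	3	38	20	18
scaRNA	6	6	0	11	6	5
snRNA	8	6	2	25	13	12
scRNA	2	0	2	19	14	5
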