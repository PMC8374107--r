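category	ev_n	cell_n
canonical	52	10
shorter_3p	33	12
shorter_5p	4	0
longer_3p	23	1
longer_5p	7	1
shifted_toward_3p	8	0
shifted_toward_5p	4	1
shorter_both	2	0
opposite_arm	6	2
trailer	6	5
stem_loop	3	5
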