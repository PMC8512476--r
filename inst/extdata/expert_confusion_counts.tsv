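group	n_ics	segments	tp	tn	fp	fn
G1	21	20	53	362	1	4
G2	20	20	41	352	0	7
G3	19	20	22	333	0	25
G1s	21	20	46	371	0	3
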