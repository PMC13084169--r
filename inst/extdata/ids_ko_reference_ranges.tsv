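reaction_id	subsystem	wt_min	wt_max	ko_min	ko_max
MAR07517	CS degradation	0	140.00	0	0
MAR07241	HS degradation	0	67.68	0	0
MAR07247	HS degradation	0	67.68	0	0
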