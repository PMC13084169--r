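quantity	value
total_reactions	12971
above_threshold_reactions	42
noise_excluded_reactions	2
affected_reactions	40
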