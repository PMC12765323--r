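scope	tp	fp	tn	fn	ambig_p	ambig_b
cohort	1252	133	2115	325	219	160
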