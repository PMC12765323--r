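predicted_class	n
benign	89408
ambiguous	12248
pathogenic	26592
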