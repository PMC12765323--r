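gene	protein_change	allele_frequency	homozygote_count	cadd_phred
ABCA4	Pro1948Leu	3.93e-2	1534	23.5
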