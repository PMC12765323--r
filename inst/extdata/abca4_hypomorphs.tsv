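gene	protein_change	am_pathogenicity	allele_frequency	homozygote_count	cadd_phred
ABCA4	Gly863Ala	0.343	7.06e-3	46	31.0
ABCA4	Ala1038Val	0.164	1.85e-3	7	19.9
ABCA4	Pro1486Leu	0.201	3.79e-5	0	24.8
ABCA4	Thr1526Met	0.366	1.23e-4	0	25.2
ABCA4	Ile1562Thr	0.180	1.56e-3	3	22.9
ABCA4	Asn1868Ile	0.223	5.58e-2	2989	23.3
ABCA4	Gly1961Glu	0.853	3.41e-3	44	26.2
ABCA4	Arg2030Gln	0.106	4.77e-4	0	27.2
ABCA4	Arg2107His	0.326	1.15e-3	17	29.3
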