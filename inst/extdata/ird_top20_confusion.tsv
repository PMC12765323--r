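gene	tp	fn	tn	fp
ABCA4	217	80	22	0
USH2A	97	46	118	0
RPGR	1	1	34	0
PRPH2	29	8	1	0
BEST1	50	10	6	1
RS1	23	1	7	0
RP1	5	1	28	1
RHO	29	4	5	1
CHM	1	0	24	3
CRB1	44	26	14	1
PRPF31	1	0	0	0
MYO7A	83	3	29	5
OPA1	1	0	13	3
CNGB3	8	2	18	1
RPE65	59	5	5	1
EYS	9	4	43	1
GUCY2D	19	1	13	0
PROM1	0	3	5	1
CNGA3	50	10	15	0
RDH12	28	6	2	0
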