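# Reference table: distribution of identified proteins over the six Rlv UPM791
# replicons (published summary of the pea/lentil bacteroid proteome comparison;
# counts and bracketed percentages as printed). *_pct columns are the printed
# percentages; genome percentages are referred to the printed total of 7318.
replicon	genome	vegetative	pea	pea_specific	lentil	lentil_specific	genome_pct	vegetative_pct	pea_pct	lentil_pct
Chromosome	4587	1154	901	12	891	13	62.7	87.1	81.6	85.3
pRlvA	1246	62	50	4	42	8	17.0	4.7	4.5	4.0
pRlvB	588	44	50	3	35	2	8.0	3.3	4.5	3.3
pRlvC	366	10	68	7	50	1	5.0	0.7	6.2	4.8
pRlvD	239	8	3	0	4	0	3.3	0.6	0.3	0.4
pRlvE	545	46	32	2	22	1	7.4	3.5	2.9	2.1
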