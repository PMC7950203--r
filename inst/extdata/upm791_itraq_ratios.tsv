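# Reference table: the 36 published iTRAQ pea/lentil ratios of the Rlv UPM791
# bacteroid comparison, with the section (pea- or lentil-overexpressed) each
# protein was printed under.
accession	replicon	ratio	printed_group
RLV_1136	pRlvA	2.62	pea_over
RLV_1140	pRlvA	2.60	pea_over
RLV_1141	pRlvA	2.20	pea_over
RLV_1384	pRlvB	2.10	pea_over
RLV_1399	pRlvB	2.00	pea_over
RLV_1404	pRlvB	2.24	pea_over
RLV_1805	pRlvC	2.45	pea_over
RLV_1815A	pRlvC	2.06	pea_over
RLV_1821	pRlvC	2.23	pea_over
RLV_1826	pRlvC	2.29	pea_over
RLV_1843A	pRlvC	3.22	pea_over
RLV_1844	pRlvC	2.41	pea_over
RLV_1845	pRlvC	2.86	pea_over
RLV_1846	pRlvC	3.77	pea_over
RLV_1848	pRlvC	2.88	pea_over
RLV_1849	pRlvC	2.66	pea_over
RLV_1887	pRlvC	2.35	pea_over
RLV_1889	pRlvC	2.12	pea_over
RLV_1961	pRlvC	2.42	pea_over
RLV_1979	pRlvC	2.39	pea_over
RLV_4347	Chromosome	3.02	pea_over
RLV_4576A	Chromosome	2.34	pea_over
RLV_4577	Chromosome	2.16	pea_over
RLV_4675	Chromosome	2.16	pea_over
RLV_5449	Chromosome	2.66	pea_over
RLV_7044	Chromosome	2.24	pea_over
RLV_7109	Chromosome	3.24	pea_over
RLV_7281	Chromosome	2.04	pea_over
RLV_502	pRlvA	0.36	lentil_over
RLV_817	pRlvA	0.17	lentil_over
RLV_818	pRlvA	0.45	lentil_over
RLV_1833	pRlvC	0.34	lentil_over
RLV_1892	pRlvC	0.42	lentil_over
RLV_1894	pRlvC	0.39	lentil_over
RLV_1896	pRlvC	0.39	lentil_over
RLV_5494	Chromosome	0.50	lentil_over
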