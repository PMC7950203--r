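# Reference table: published symbiotic-performance means (four replicates,
# +/- standard error) for pea and lentil plants inoculated with Rlv UPM791,
# its gntR (RLV_1934A) mutant UPM1418, and the complemented strain UPM1419.
strain	host	shoot_dw	shoot_dw_se	n_fixed	n_fixed_se
Control	pea	162.4	4.3	2.22	1.28
UPM791	pea	482.9	48.5	21.96	12.68
UPM1418	pea	347.8	26.4	15.74	9.09
UPM1419	pea	327.9	35.4	15.31	8.84
Control	lentil	113.8	10.4	1.42	0.11
UPM791	lentil	283.9	14.5	7.22	0.42
UPM1418	lentil	235.4	12.2	6.39	0.25
UPM1419	lentil	209.5	26.9	5.87	0.69
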