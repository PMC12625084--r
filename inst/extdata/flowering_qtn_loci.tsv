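id	chrom	pos
Lu11_3283122	Lu11	3283122
Lu11_1592089	Lu11	1592089
Lu12_2899524	Lu12	2899524
Lu12_4359290	Lu12	4359290
Lu03_8373065	Lu03	8373065
Lu03_7400113	Lu03	7400113
Lu15_2036006	Lu15	2036006
Lu15_1756429	Lu15	1756429
Lu4_16669798	Lu4	16669798
Lu4_9221348	Lu4	9221348
Lu01_6408072	Lu01	6408072
Lu13_17577340	Lu13	17577340
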