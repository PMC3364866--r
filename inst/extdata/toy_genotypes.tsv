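individual_id	species	locality	snp01	snp02	snp03	snp04	snp05	snp06
D01	mallard	lakeA	2	2	0	2	0	2
D02	mallard	lakeA	0	0	2	0	NA	2
D03	mallard	lakeA	1	2	0	1	1	1
D04	mallard	lakeA	1	NA	0	2	1	0
D05	pintail	lakeB	1	1	0	0	0	2
D06	pintail	lakeB	1	1	0	0	NA	0
D07	teal	lakeB	0	0	1	0	0	0
D08	teal	lakeB	0	2	2	0	1	0
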