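sample	species	locality
S1	mallard	lakeA
S2	mallard	lakeA
S3	pintail	lakeB
S4	pintail	lakeB
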