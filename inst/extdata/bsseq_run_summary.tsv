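sample	raw_reads	clean_reads	clean_bases	coverage
DQ	594788152	590823228	83104198973	24
XL	533428824	530497464	74392650272	21
BQ3	756520682	748641934	105687219276	30
GND7	737454714	726820566	100823741986	29
NC3	646283200	641575332	91217851918	26
NC6	681142904	676647870	96284006901	28
Z0119	606827696	604717660	86834819607	25
Z0226	580123472	577851246	82416533291	24
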