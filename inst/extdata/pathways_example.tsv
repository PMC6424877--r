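# kefirmg schema: pathway_definitions v1 (illustrative gene lists, synthetic)
pathway	gene
L-lysine	lysC
L-lysine	asd
L-lysine	dapA
L-lysine	dapB
L-lysine	lysA
L-threonine	lysC
L-threonine	hom
L-threonine	thrB
L-threonine	thrC
L-tryptophan	trpA
L-tryptophan	trpB
L-tryptophan	trpC
L-tryptophan	trpD
L-tryptophan	trpE
riboflavin	ribA
riboflavin	ribB
riboflavin	ribE
riboflavin	ribH
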