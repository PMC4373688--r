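species	rcbs	enc	gc3s	fop	highest_rscu_codon	highest_rscu_aa	gc_skew	gc3_skew
Tupaia chinensis	0.006	54	0.68	0.305	CTG	Leu	-0.08	0.061
Bos taurus	0.015	56	0.65	0.305	CTG	Leu	-0.11	0.071
Felis catus	0.03	53	0.69	0.305	CTG	Leu	-0.06	0
Canis lupus	0.042	56	0.65	0.305	CTG	Leu	-0.08	0.076
Meriones unguiculatus	0.043	52	0.71	0.306	CTG	Leu	-0.09	0.094
Rattus norvegicus	0.054	59	0.59	0.306	CTG	Leu	-0.06	0.026
Macaca mulatta	0.063	57	0.62	0.305	CTG	Leu	-0.10	0.081
Homo sapiens	0.065	57	0.62	0.305	CTG	Leu	-0.09	0.065
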