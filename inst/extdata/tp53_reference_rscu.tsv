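amino_acid	codon	n	rscu_mean
Ala	GCA	37	0.78
Ala	GCC	91	1.95
Ala	GCG	26	0.53
Ala	GCT	36	0.76
Arg	CGT	34	0.98
Arg	CGC	65	1.86
Arg	CGA	27	0.78
Arg	CGG	33	0.96
Arg	AGA	24	0.71
Arg	AGG	25	0.73
Asn	AAC	68	1.2
Asn	AAT	44	0.81
Asp	GAT	67	0.86
Asp	GAC	82	1.15
Cys	TGC	60	1.31
Cys	TGT	32	0.69
Gln	CAA	23	0.43
Gln	CAG	82	1.57
Glu	GAA	84	0.7
Glu	GAG	157	1.31
Gly	GGA	41	0.95
Gly	GGC	49	1.13
Gly	GGG	65	1.5
Gly	GGT	18	0.43
His	CAT	32	0.78
His	CAC	50	1.23
Ile	ATA	0	0
Ile	ATC	61	2.58
Ile	ATT	11	0.43
Leu	TTA	9	0.2
Leu	TTG	31	0.71
Leu	CTA	17	0.38
Leu	CTC	39	0.88
Leu	CTG	143	3.18
Leu	CTT	30	0.68
Lys	AAA	42	0.51
Lys	AAG	125	1.5
Phe	TTT	29	0.63
Phe	TTC	61	1.37
Pro	CCA	70	0.84
Pro	CCC	115	1.4
Pro	CCG	44	0.55
Pro	CCT	100	1.22
Ser	TCA	45	0.86
Ser	TCC	94	1.81
Ser	TCG	21	0.4
Ser	TCT	58	1.09
Ser	AGC	66	1.26
Ser	AGT	30	0.57
Thr	ACA	47	1.05
Thr	ACC	84	1.91
Thr	ACG	18	0.4
Thr	ACT	29	0.65
Tyr	TAC	45	1.19
Tyr	TAT	32	0.81
Val	GTA	5	0.15
Val	GTC	38	1.1
Val	GTG	69	1.98
Val	GTT	28	0.8
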