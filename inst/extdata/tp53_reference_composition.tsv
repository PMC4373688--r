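species	accession	length_bp	A	T	G	C	A3	T3	G3	C3	AT_pct	GC_pct	GC1	GC2	GC3	AT3_pct	GC12
Tupaia chinensis	KF921494.1	1152	262	224	308	358	55	69	122	138	42.2	57.8	56.8	49.0	67.7	32.3	52.9
Bos taurus	AB571118.1	1161	267	234	294	366	56	79	117	135	43.2	56.8	56.8	48.6	65.1	34.9	52.7
Felis catus	KJ511263.1	1161	261	219	321	360	53	66	134	134	41.3	58.7	57.4	49.4	69.3	30.7	53.4
Canis lupus	KJ511265.1	1146	266	229	300	351	55	78	115	134	43.2	56.8	56.5	48.7	65.2	34.8	52.6
Meriones unguiculatus	AB033632.1	1173	264	204	321	384	57	58	125	151	39.9	60.1	59.8	49.9	70.6	29.4	54.9
Rattus norvegicus	BC098663.1	1176	289	244	302	341	73	89	112	118	45.3	54.7	57.4	48.0	58.7	41.3	52.7
Macaca mulatta	HM104191.1	1182	282	232	301	367	68	82	112	132	43.5	56.5	58.1	49.5	61.9	38.1	53.8
Homo sapiens	U94788.1	1182	276	234	307	365	62	86	115	131	43.1	56.9	59.1	49.0	62.4	37.6	54.1
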