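# Per-accession structural-variant counts from long-read sequencing of 10
# soybean accessions (per-type counts; Total printed in the source table).
accession	group	INS	DEL	DUP	INV	TRA	INVDUP	printed_total
Peking	Primitive	7388	8975	370	97	1092	0	17922
Moshidou Gong 503	Primitive	10959	12475	356	106	1106	0	25002
C1329	World	3878	4348	156	47	698	1	9128
PK 73-54	World	2645	2885	166	44	632	1	6373
5002T	World	2151	2454	126	47	557	0	5335
Williams 82	World	785	452	132	41	623	0	2033
Houjaku Kuwazu	Japan	6254	6671	356	100	1011	0	14392
Enrei	Japan	6432	7043	370	90	985	1	14921
Fukuyutaka	Japan	6764	7458	348	92	1315	5	15982
Misuzudaizu	Japan	2486	2821	143	46	648	0	6144
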