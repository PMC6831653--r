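group	region	n_species	n_endemic
fishes	AZO	165	1
fishes	MAD	208	0
fishes	SEL	76	0
fishes	CAN	299	2
fishes	CAB	303	22
echinoderms	AZO	64	0
echinoderms	MAD	69	0
echinoderms	SEL	18	0
echinoderms	CAN	85	0
echinoderms	CAB	76	1
gastropods	AZO	280	37
gastropods	MAD	397	14
gastropods	SEL	207	3
gastropods	CAN	811	96
gastropods	CAB	608	268
brachyurans	AZO	62	0
brachyurans	MAD	75	0
brachyurans	CAN	120	0
brachyurans	CAB	117	10
polychaetes	AZO	169	1
polychaetes	MAD	300	10
polychaetes	SEL	86	0
polychaetes	CAN	465	10
polychaetes	CAB	213	9
macroalgae	AZO	405	0
macroalgae	MAD	396	1
macroalgae	SEL	295	0
macroalgae	CAN	689	1
macroalgae	CAB	333	0
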