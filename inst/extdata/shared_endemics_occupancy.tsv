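group	occupancy	n
fishes	5	6
fishes	4	2
fishes	3	5
fishes	2	0
echinoderms	5	0
echinoderms	4	0
echinoderms	3	0
echinoderms	2	0
gastropods	5	3
gastropods	4	10
gastropods	3	35
gastropods	2	56
brachyurans	5	0
brachyurans	4	2
brachyurans	3	0
brachyurans	2	5
polychaetes	5	0
polychaetes	4	0
polychaetes	3	3
polychaetes	2	6
macroalgae	5	1
macroalgae	4	3
macroalgae	3	4
macroalgae	2	9
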