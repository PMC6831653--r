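group	n_total	n_widespread
fishes	465	39
echinoderms	152	9
gastropods	1312	44
brachyurans	177	31
polychaetes	683	18
macroalgae	949	99
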