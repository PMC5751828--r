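profile,n,icu,los_ge5
Haemophilus-dominant,59,16,19
Moraxella-dominant,106,6,16
Staphylococcus-dominant,363,47,47
Corynebacterium-dominant,109,20,10
Enterobacter-dominant,61,13,8
Mixed,117,21,18
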