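taxon	i-shotgun-live-1	i-shotgun-control_live-1
Bacillus velezensis	151200	201000
Escherichia coli	252300	199400
Lactococcus lactis	210500	200800
Pseudomonas_E proteolytica	190800	200100
Staphylococcus hominis	101100	199900
Acinetobacter	310	405
Corynebacterium	95	180
Streptococcus	202	215
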