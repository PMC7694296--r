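replicon_id	length	mean_depth	role
Chromosome	2021843	339.8	chromosome
pTTHNP2	9799	448.2	plasmid
pTTHNP3	77135	130.5	megaplasmid
pTTHNP4	370865	464.9	megaplasmid
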