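phylum	n_sequences	n_mcf	n_insertion
Bacteroidetes	46	44	43
Proteobacteria	144	16	11
Actinobacteria	24	6	0
Ascomycota	23	6	0
Verrucomicrobia	4	4	4
Chordata	4	3	0
Basidiomycota	3	2	0
Chlamydiae	4	2	2
Planctomycetes	11	2	0
Gemmatimonadetes	2	1	0
Ignavibacteriae	2	1	1
Nitrospirae	3	1	0
Spirochaetes	4	1	0
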