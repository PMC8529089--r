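group	environment	n_species	n_mcf
aquatic	aquatic_freshwater	69	18
aquatic	aquatic_marine	57	15
aquatic	aquatic_hot_spring	24	3
aquatic	aquatic_undefined	10	1
terrestrial	terrestrial_soil	71	23
terrestrial	terrestrial_geological	4	0
host	host_human	29	2
host	host_bovine	6	0
host	host_plants	11	3
host	host_other	35	11
industry	industry_acid_mine	4	0
industry	industry_wastewater	7	1
industry	industry_food	7	1
industry	industry_other	8	0
other	other	7	2
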