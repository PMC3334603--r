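expression_class	region_kind	n_sense_alus	n_antisense_alus	n_hits_in_sense_alus	n_hits_in_antisense_alus
up	upstream5kb	2301	2393	112	481
up	genic	14580	17507	632	3629
down	upstream5kb	6244	7187	268	1512
down	genic	47295	63323	1961	13092
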