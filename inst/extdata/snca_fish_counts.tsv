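disease	region	cell_type	n_analysed	n_gain	cohort
MSA	CC	neuron	1359	38	current
MSA	CC	non_neuron	1513	23	current
MSA	SN	NM_pos	1282	41	current
MSA	SN	NM_neg	3397	103	current
PD	CC	neuron	2533	58	current
PD	CC	non_neuron	2851	33	current
LB	CC	neuron	249	7	current
LB	CC	non_neuron	296	2	current
LB	SN	NM_pos	411	13	current
LB	SN	NM_neg	897	21	current
control	CC	neuron	1702	19	current
control	CC	non_neuron	2028	16	current
control	SN	NM_pos	3532	15	prior_control
control	SN	NM_neg	7611	19	prior_control
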