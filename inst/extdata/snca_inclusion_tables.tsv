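stratum	disease	cell_type	a	b	c	d
msa_snd_nm_pos	MSA-SND	NM_pos	1	12	36	553
msa_snd_nm_neg	MSA-SND	NM_neg	12	24	95	1090
lb_nm_pos	LB	NM_pos	4	7	24	374
lb_nm_neg	LB	NM_neg	0	17	17	851
pooled	Total	Both	17	60	172	2868
olig2_gain	MSA-SND	olig2	19	203	7	303
pons_non_neuron	MSA	non_neuron	3	2	20	154
pons_neuron	MSA	neuron	3	5	18	74
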