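species	status	het_genome_per_kb	het_exon_per_kb	ns_s
crested_ibis	EV	0.43	0.24	0.69
little_egret	LC	2.51	0.92	0.41
dalmatian_pelican	EV	0.60	0.34	0.84
great_black_cormorant	LC	1.39	0.56	0.57
kea	EV	0.91	0.45	0.63
budgerigar	LC	4.31	2.21	0.32
bald_eagle	EV	0.43	0.22	0.84
white_tailed_eagle	EV	0.40	0.21	0.80
turkey_vulture	LC	1.18	0.59	0.58
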