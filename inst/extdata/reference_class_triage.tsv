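atrophy_class	true_structure	putative_homolog	false_positive	unknown
n_terminal_end_bounded	6	34	377	82
c_terminal_end_bounded	0	26	337	105
upstream_domain_bounded	0	0	118	7
downstream_domain_bounded	2	3	311	15
within_domain	0	4	144	65
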