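quantity	value
sequences_total	23193494
sequences_with_domains	18523877
sequences_pe1	77305
sequences_pe1_nonfragment	75435
domain_instances_scored	114303
domain_instances_total	28738352
domain_families	14831
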