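failure_mode	n
gene_prediction_error	9
nested_domain	268
multi_domain_family	316
small_domain	173
circular_permutation	54
short_repeat	112
disordered_domain	85
theoretical_model	9
no_reference_structure	27
complete_structural_domain	234
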