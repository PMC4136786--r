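patient	n_point_mutations
SWE-54	27
BC_A	26
BC_B	184
BC_C	17
BC_D	245
BC_E	20
BC_F	82
BC_G	47
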