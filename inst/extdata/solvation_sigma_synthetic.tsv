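atom_type	sigma
C	0.016
N	-0.006
O	-0.006
S	0.021
N_charged	-0.05
O_charged	-0.024
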