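# synthetic derivatization standards fixture: delta_derivatized constructed
# by exact mass balance from delta_known and an assumed added-carbon delta
# of -28.0 permil
aa_code	n_carbon	n_added_carbon	delta_known	delta_derivatized
Thr	4	7	-12.0	-22.181818
Lys	6	7	-14.0	-21.538462
Phe	9	5	-16.0	-20.285714
Val	5	5	-11.0	-19.500000
Ile	6	5	-13.0	-19.818182
Leu	6	5	-15.0	-20.909091
Asp	4	8	-10.0	-22.000000
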