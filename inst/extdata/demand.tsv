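# metabolic demand for rapidly growing mice as percent of dry food;
# representative placeholder values
aa	value
Thr	0.40
Lys	0.40
Phe	0.76
Val	0.50
Ile	0.40
Leu	0.70
Asp	1.20
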