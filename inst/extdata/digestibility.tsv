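# representative true ileal digestibility for casein-based diets;
# configurable placeholder values
aa	value
Thr	0.89
Lys	0.94
Phe	0.93
Val	0.92
Ile	0.92
Leu	0.95
Asp	0.91
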