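# fraction of each dietary amino acid catabolized by intestinal mucosa
# before reaching the systemic pool (non-ruminant, casein diets)
aa	value
Ile	0.30
Leu	0.40
Val	0.40
Phe	0.45
Lys	0.50
Thr	0.60
Asp	0.85
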