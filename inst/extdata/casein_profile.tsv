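# representative casein amino acid composition (g AA per g protein);
# configurable placeholder values, not asserted study measurements
aa	concentration
Thr	0.042
Lys	0.078
Phe	0.050
Val	0.066
Ile	0.054
Leu	0.095
Asp	0.068
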