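# representative cornmeal (maize) protein composition (g AA per g protein);
# configurable placeholder values
aa	concentration
Thr	0.035
Lys	0.028
Phe	0.049
Val	0.047
Ile	0.036
Leu	0.122
Asp	0.065
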