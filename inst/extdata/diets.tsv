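treatment_label	mass_fraction_casein	mass_fraction_sucrose	mass_fraction_cornmeal	cornmeal_protein_fraction	delta_casein	delta_sucrose	delta_cornmeal
40P:40C	0.396	0.36	0.04	0.10	-26.5	-12.2	-12.0
21P:45C	0.201	0.36	0.09	0.10	-26.5	-12.2	-12.0
12P:55C	0.101	0.36	0.19	0.10	-26.5	-12.2	-12.0
9P:75C	0.051	0.36	0.39	0.10	-26.5	-12.2	-12.0
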