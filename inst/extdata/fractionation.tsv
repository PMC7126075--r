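# microbial de novo synthesis fractionation offsets (permil vs carbohydrate
# substrate pool); configurable placeholders of realistic magnitude
aa	offset
Thr	-1.0
Lys	-2.0
Phe	-3.5
Val	-3.0
Ile	-2.5
Leu	-4.0
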