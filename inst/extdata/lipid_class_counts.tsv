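class	n_species
GP_GL	172
SL	19
FA	14
PR	1
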