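quantity	value
n_as_genes	262
n_mapped_ests	46153
frac_introns_gt200	0.05
cneoformans_variants	1091
cneoformans_ests	59041
mgrisea_variants	151
mgrisea_ests	53102
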