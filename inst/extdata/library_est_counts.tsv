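library	day	karyotype	filtered	mapped	spliced
5D_36123	5	dikaryon	1001	964	828
14D_36123	14	dikaryon	6848	6701	5820
18D_36123	18	dikaryon	21547	21078	17455
18D_37180	18	monokaryon	11059	10782	8944
30D_36123	30	dikaryon	6830	6628	5348
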