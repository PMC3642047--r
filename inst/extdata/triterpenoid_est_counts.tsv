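gene_id	description	5D_36123	14D_36123	18D_36123	18D_37180	30D_36123
YMGLESTG49648	acetyl-CoA acetyltransferase	0	5	33	3	12
YMGLESTG52067	3-hydroxy-3-methylglutaryl-CoA synthase	0	2	68	9	12
YMGLESTG53675	3-hydroxy-3-methylglutaryl-coenzyme A reductase	0	0	16	1	4
YMGLESTG52428	beta-cystathionase	0	0	1	1	1
YMGLESTG50562	phosphomevalonate kinase	0	0	2	0	0
YMGLESTG50973	mevalonate pyrophosphate decarboxylase	0	1	5	1	1
YMGLESTG47454	isopentenyl-diphosphate isomerase	0	4	3	0	6
YMGLESTG55240	farnesyl pyrophosphate synthase	0	0	8	0	2
YMGLESTG52116	farnesyl pyrophosphate synthase	0	0	11	4	8
YMGLESTG51888	squalene synthase	0	2	3	5	4
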