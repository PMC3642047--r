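from	to	n_genes
0	0	6912
1	49	7033
50	99	85
100	149	13
150	199	5
200	249	2
250	299	0
300	349	0
350	399	2
579	579	1
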