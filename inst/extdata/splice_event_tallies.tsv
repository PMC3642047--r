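event_class	exon_count	n_events
skipped	1	15
skipped	11	1
retained	1	246
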