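primer_id	target_locus	role	sequence
qPCR_mei4_DSR_F	mei4_DSR	target_forward	CTTCAAATGTTGCTGCCGAAG
qPCR_mei4_DSR_R	mei4_DSR	target_reverse	GAGTTTCAGCATTTGGTTTAGG
cdc2.2_F	cdc2	reference_forward	CCACTGGGGTTGATATTTGG
cdc2.2_R	cdc2	reference_reverse	CGTTTCCAACGAGGAAATGT
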