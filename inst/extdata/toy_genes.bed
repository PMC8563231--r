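1	200000	400000	GENE_A
1	650000	780000	GENE_B
1	1100000	1250000	GENE_C
2	300000	450000	GENE_D
2	820000	900000	GENE_E
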