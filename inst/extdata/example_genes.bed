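1	49999	120000	GENE1	0	+
1	150000	180000	GENE2	0	+
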