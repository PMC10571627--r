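pathway	size	es	nes	pval	padj
planted_down	12	-0.776256477699543	-1.87233265488294	0.0036231884057971	0.0176991150442478
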