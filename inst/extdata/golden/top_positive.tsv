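pathway	size	es	nes	pval	padj
planted_up	12	0.758922303896845	1.97888681162904	0.00442477876106195	0.0176991150442478
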