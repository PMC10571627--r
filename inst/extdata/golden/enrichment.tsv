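pathway	pval	padj	es	nes	size	leading_edge
planted_down	0.003623188406	0.01769911504	-0.7762564777	-1.872332655	12	g00013,g00021,g00018,g00015,g00023,g00020,g00014,g00017,g00022
planted_up	0.004424778761	0.01769911504	0.7589223039	1.978886812	12	g00011,g00007,g00001,g00005,g00008,g00010,g00003,g00009,g00004
decoy_04	0.3224637681	0.6637168142	-0.4604561171	-1.110621359	12	g00042,g00028
decoy_03	0.3318584071	0.6637168142	0.4211819037	1.098230096	12	g00096,g00060
decoy_06	0.4311594203	0.6898550725	-0.4294983638	-1.035951177	12	g00097,g00064
decoy_01	0.796460177	0.9492753623	0.2973233115	0.7752693219	12	g00096
decoy_05	0.8623188406	0.9492753623	-0.2902287206	-0.7000324333	12	g00090,g00109,g00051,g00049,g00027
decoy_02	0.9492753623	0.9492753623	-0.2456804192	-0.5925818137	12	g00042
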