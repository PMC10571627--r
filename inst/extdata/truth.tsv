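gene	set	beta	log2fc
g00001	planted_up	1	1
g00002	planted_up	1	1
g00003	planted_up	1	1
g00004	planted_up	1	1
g00005	planted_up	1	1
g00006	planted_up	1	1
g00007	planted_up	1	1
g00008	planted_up	1	1
g00009	planted_up	1	1
g00010	planted_up	1	1
g00011	planted_up	1	1
g00012	planted_up	1	1
g00013	planted_down	-1	-1
g00014	planted_down	-1	-1
g00015	planted_down	-1	-1
g00016	planted_down	-1	-1
g00017	planted_down	-1	-1
g00018	planted_down	-1	-1
g00019	planted_down	-1	-1
g00020	planted_down	-1	-1
g00021	planted_down	-1	-1
g00022	planted_down	-1	-1
g00023	planted_down	-1	-1
g00024	planted_down	-1	-1
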