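planted_up	planted	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008	g00009	g00010	g00011	g00012
planted_down	planted	g00013	g00014	g00015	g00016	g00017	g00018	g00019	g00020	g00021	g00022	g00023	g00024
decoy_01	decoy	g00037	g00047	g00062	g00068	g00078	g00083	g00096	g00101	g00112	g00113	g00117	g00119
decoy_02	decoy	g00040	g00042	g00045	g00056	g00070	g00080	g00084	g00087	g00090	g00102	g00103	g00119
decoy_03	decoy	g00038	g00039	g00059	g00060	g00062	g00068	g00070	g00074	g00080	g00096	g00102	g00111
decoy_04	decoy	g00028	g00035	g00040	g00042	g00046	g00059	g00068	g00071	g00073	g00079	g00081	g00093
decoy_05	decoy	g00027	g00043	g00047	g00049	g00051	g00052	g00071	g00082	g00089	g00090	g00109	g00114
decoy_06	decoy	g00029	g00031	g00040	g00047	g00051	g00062	g00064	g00071	g00097	g00105	g00108	g00110
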