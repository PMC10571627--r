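sample	time	status
s0001	0.00445967226292659	1
s0002	0.00242115993796137	1
s0003	0.262295137884606	1
s0004	4.07997968130362	0
s0005	0.0735069555462587	1
s0006	42.3256790469906	1
s0007	2.34843190297934	1
s0008	22.4302112872073	1
s0009	185.900325887637	0
s0010	0.124908722016751	1
s0011	64.9338914870394	0
s0012	0.000930095080421509	1
s0013	0.0651796443825936	1
s0014	9.01311085910774	1
s0015	3.52095391633138	1
s0016	90.2510293262562	0
s0017	56.9851083977579	0
s0018	141.772786325878	0
s0019	3.69305082419494	1
s0020	38.4019401127681	1
s0021	3.68167871679883	1
s0022	0.000881667882374217	1
s0023	0.741967998318702	1
s0024	0.628290896926338	1
s0025	0.0491394240098131	1
s0026	144.570345103287	1
s0027	0.0333799283292826	1
s0028	128.639696994879	0
s0029	24.0753381272698	1
s0030	178.22718324104	0
s0031	0.0204754354352792	1
s0032	0.246595965379887	1
s0033	166.831458163434	0
s0034	0.0385176713904699	1
s0035	0.0243142082463274	1
s0036	103.419920831766	0
s0037	251.610882874076	0
s0038	19.8576399938292	1
s0039	121.780547249924	0
s0040	0.534613732687017	1
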