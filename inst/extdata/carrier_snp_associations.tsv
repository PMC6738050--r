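rsid	chrom	pos	gene	ref_allele	effect_allele	eaf	info	log_hr	se	p	trait
rs11049611	12	28600244	CCDC91	C	T	0.28	1	0.127	0.036	0.0004	height
rs6902771	6	152157881	ESR1	C	T	0.46	0.98	0.091	0.032	0.005	height
rs584828	17	38599230	IGFBP4	C	T	0.39	0.68	0.109	0.040	0.006	height
rs3817428	15	89415247	ACAN	C	G	0.22	0.51	0.144	0.053	0.006	height
rs7517682	1	103519589	COL11A1	G	A	0.56	0.98	0.085	0.033	0.009	height
rs12470505	2	219908369	CCDC108	T	G	0.10	0.97	-0.143	0.055	0.009	height
rs26024	5	127696022	FBN2	A	C	0.34	1	-0.087	0.034	0.011	height
rs13113518	4	56399648	CLOCK	T	C	0.37	0.99	0.081	0.033	0.014	height
rs7319045	13	92024574	GPC5	A	G	0.61	0.92	0.084	0.035	0.017	height
rs2044124	17	61845425	CCDC47	T	C	0.95	0.91	0.187	0.079	0.018	height
rs930910	2	43629612	THADA	A	G	0.35	1	0.076	0.033	0.021	height
rs11867943	17	54229842	ANKFN1	A	T	0.11	0.96	0.118	0.051	0.022	height
rs12779328	10	12943973	CCDC3	C	T	0.30	0.94	-0.080	0.036	0.026	height
rs8073371	17	46096276	COPZ2	C	T	0.20	1.00	-0.095	0.043	0.029	height
rs2013265	8	24092500	ADAM28	C	T	0.22	0.62	0.104	0.047	0.029	height
rs11687941	2	242191410	HDLBP	C	G	0.26	0.96	-0.079	0.037	0.031	height
rs6838153	4	122720999	EXOSC9	A	G	0.33	0.99	-0.072	0.034	0.033	height
rs7112925	11	66826160	RHOD	C	T	0.36	0.95	-0.071	0.034	0.037	height
rs16942341	15	89388905	ACAN	C	T	0.03	0.60	0.255	0.123	0.039	height
rs6080830	20	17771113	BANF2	A	G	0.43	0.68	-0.080	0.039	0.041	height
rs867245	4	2218888	POLN	C	G	0.07	1.00	0.122	0.060	0.043	height
rs1155939	6	126866133	C6orf173	C	A	0.51	0.99	0.064	0.033	0.049	height
rs16851483	3	141275436	RASA2	G	T	0.07	1	-0.203	0.068	0.003	bmi
rs2207139	6	50845490	TFAP2B	A	G	0.16	0.99	0.120	0.043	0.005	bmi
rs2033732	8	85079709	RALYL	T	C	0.75	0.72	-0.088	0.042	0.037	bmi
rs6804842	3	25106437	RARB	A	G	0.58	0.58	0.087	0.044	0.046	bmi
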