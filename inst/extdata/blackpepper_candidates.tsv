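sl_no	unigene_id	ssr_motif	premirna_start	premirna_end	delta_g	direction	mature_start	mature_end	mature_seq	au_content
1	2414	TCC	184	303	41.8	Plus	230	251	AGCGCGAGUUCGCCUUCGCCGU	31.82
2	2535	CGG	8	127	44.29	Plus	67	88	UGCAGCGGUUUGGGAGGAGGGG	31.82
3	3169	AG	218	337	33.2	Minus	282	302	AUGCCGUCUUUCUGGGGUGAG	42.86
4	11980	AG,GGT	37	156	48.18	Minus	114	135	CCUCCUUCUUCGCCUUCCCCCU	36.36
5	12508	AG,TG	78	197	35.3	Minus	88	108	UCUUGGGGGUUGGGGUGAGAG	38.10
6	25668	TCG	126	245	40.4	Plus	172	293	AAGGCUGUGAUGGACGUUUUUG	54.55
7	26112	CCT,AGG	195	314	39.6	Minus	246	267	GGCACCGACGCCAGGGUGUUGU	31.82
8	30088	CTC	34	153	52.4	Plus	111	132	UUGUCGGAGGUGUCGCCAGCGU	36.36
9	31243	CCG	240	359	37.0	Plus	272	292	GGGAGCUUGUUGGUGAUGGUC	42.86
10	32324	GGC	19	138	50.7	Minus	47	68	CUCUAGCACCUUCUCCACUCCG	40.91
11	45182	ACA	229	348	32.6	Minus	283	304	CAAUACUAUGAGCUUGAAUUGG	63.64
12	49665	AAG	147	266	37.9	Plus	243	263	AUGGGGACAACGCAGGUGUUG	42.86
13	49856a	AT	552	671	47.67	Minus	580	500	CAAAUGAACAAUAUAAUUACG	76.19
14	49856b	AT	51	170	37.18	Minus	56	76	UCCUCCACCGUGUAGCUCAUG	42.86
15	49856c	AT	40	159	34.08	Minus	139	159	GCUGCCUGUGGUAGAAUGCGU	42.86
16	50113a	CCT	270	389	41.3	Plus	307	328	AGGAUGAGUUGAAGAAGUUGGU	59.10
17	50113b	CCT	248	367	40.5	Minus	324	345	CGUCGGUGUCGGCCACCACCAA	31.82
18	50626	GAG	77	196	51.1	Minus	113	134	CCAUCGCUGAGCUCGUAGUAGU	45.46
19	51352	CCG	28	147	42.34	Plus	48	69	UUGCCUCUCCUCUCCCAAAGAC	45.46
20	54811	ACC,CCG	29	148	53.86	Minus	111	132	UCACCCCAGAGGUCCGACUCGU	36.36
21	64214a	CCA	59	178	34.04	Minus	106	127	GUAGCCUUUUCGUGUCUGUGUC	50.00
22	64214b	CCA	28	147	38.3	Minus	85	106	CAGUCGAACAUUCGGGCAAGCG	40.91
23	65213	AG	42	161	37.65	Plus	84	104	UCUCUCUUUGUAAGUUUUCUG	66.67
24	72663a	AAG	70	189	36.1	Minus	96	117	AGAUUGAGCUCCUCUUCUUGGU	54.55
25	72663b	AAG	55	174	38.3	Minus	136	157	CCAUGAAUCCAGACUCGGCUGC	40.91
26	74589	AGG	122	241	36.2	Plus	184	204	GUUGGGCGGGGAGGAGAAGAU	38.10
27	88484	AG	50	169	34.5	Plus	131	151	AUCAUAUCUACUCGCUUCAAA	66.67
28	90461	AAG	130	249	46.07	Minus	138	158	ACUCCUUGGUGGUAGACGCCU	42.86
29	93292	AGG	169	288	32.74	Plus	178	198	UGAUGUUGGCGAGGUGAUGAA	52.38
30	94407	TC	216	335	38.1	Minus	245	265	CGACCAUUGCAUGACCAGGGC	38.10
31	94456	GCA	0	119	50.5	Plus	28	49	GCAUUUUGAUGGCCGAUAUGGU	54.55
32	94870	GGA	0	119	41.8	Plus	45	66	UGGGAAGCAGAGGUAUGGCCGC	36.36
33	95728	CTC	18	137	32.77	Plus	57	77	CCUUUCUUGCCGGUUGGAGGA	42.86
34	98341	TC	29	148	35.8	Minus	126	147	GAGAGAGAUGGGGGAUGUCACC	40.91
35	103545a	CGA	61	180	40.6	Plus	84	105	CUGCUCGUCGUCGGAUGGCGAA	36.36
36	103545b	CGA	89	208	42.9	Plus	112	133	GAAGUUAACUUUUCAACGCCGU	59.10
37	106552	ACG	26	145	45.66	Plus	69	90	GCUUCCACUUUGUCAUCCCCCG	40.91
38	111157	TCG	0	119	47.0	Plus	37	58	GAAGAACUCGUCGUCACCGUCG	40.91
39	118746a	GAG	112	231	44.2	Plus	158	179	CUCGCCGAUUUGAGCGGCAGCG	31.82
40	118746b	GAG	86	205	45.6	Minus	102	123	UCCUCAUCCUGCGGCUGCUCUU	40.91
41	120734a	AG	30	149	47.8	Plus	51	71	UCGAGAUGGAGGGAGGUCUGG	38.10
42	120734b	AG	133	252	50.6	Minus	189	209	UCUCCCUCUCUCUCUACUUCU	52.39
43	122117	TTG	233	352	32.0	Plus	291	312	GGGGAUCCGCCAUGAAAGCUCC	36.36
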