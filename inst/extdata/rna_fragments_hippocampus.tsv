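chrom	start	end	length	gene_5p	dist_5p	gene_3p	dist_3p	locus_id	reads_ad	reads_amc	ratio_printed	p_printed	ns	description
1	633888	634164	277	RP5-857K21.3	36389	RP5-857K21.4	0	RP5-857K21.4	515	1360	0.38	0.0001	FALSE	Transcribed processed pseudogene
1	2281959	2282363	405	SKI	0	MORN1	38889	SKI	1396	1967	0.71	0.0001	FALSE	Ski proto-oncogene
1	109100211	109100485	275	SCARNA2	0	RP5-1065J22.4	3049	SCARNA2	131	98	1.34	0.05	FALSE	Small Cajal-body specific RNA 2
1	244863775	244864066	292	RP11-11N7.5	8277	HNRNPU	0	HNRNPU	509	653	0.78	0.004	FALSE	Heterogeneous nuclear ribonucleoprotein U
2	32916221	32916538	318	LINC00486	0	AL121656.5	10588	LINC00486	17	5	3.40	0.02	FALSE	Long intergenic non-protein-coding RNA 486
2	47335292	47335571	280	CALM2	158690	AC073283.4	0	AC073283.4	2728	2093	1.30	0.0002	FALSE	Uncharacterized transcript
2	148961908	148962183	276	KIF5C	0	LYPD6B	75923	KIF5C	3055	1856	1.65	0.0001	FALSE	Kinesin family member 5C
2	181678574	181678849	276	ITGA4	142386	CERKL	0	CERKL	107	60	1.78	0.001	FALSE	Ceramide kinase like
2	231460607	231460888	282	AC017104.2	7453	NCL	0	NCL	41	27	1.52	NA	TRUE	Nucleolin
2	233275721	233275994	274	ATG16L1	0	SCARNA5	0	ATG16L1	400	206	1.94	0.0001	FALSE	Autophagy related 16-like 1; second gene in same peak: SCARNA5 (11/5 reads, ratio 2.2)
2	240713854	240714163	310	RP11-118M12.2	12168	KIF1A	0	KIF1A	2806	4988	0.56	0.0001	FALSE	Kinesin family member 1A
3	160514943	160515216	274	RNU7-136P	42526	KPNA4	0	KPNA4	536	232	2.31	0.0001	FALSE	Karyopherin (importin) subunit alpha 4
6	26204696	26204971	276	HIST1H4E	0	HIST1H2BG	11094	HIST1H4E	164	304	0.54	0.0001	FALSE	Histone 1 (AD-aggregate-enriched protein)
6	34071883	34072162	280	MIR1275	71831	GRM4	0	GRM4	10689	5521	1.94	0.0001	FALSE	Glutamate metabotropic receptor 4
6	52995648	52995925	278	RN7SK	0	ICK	5353	RN7SK	32569	12138	2.68	0.0001	FALSE	7SK RNA
6	99408034	99408309	276	COQ3	13829	PNISR	0	PNISR	206	135	1.53	0.001	FALSE	PNN interacting serine and arginine-rich protein
7	5529123	5529444	322	MIR589	33205	ACTB	0	ACTB	1210	1719	0.70	0.0001	FALSE	Beta actin (AD-aggregate-enriched protein)
7	26200464	26200741	278	CTB-119C2.1	25518	HNRNPA2B1	0	HNRNPA2B1	168	99	1.70	0.0002	FALSE	HnRNP A2/B1 (AD-aggregate-enriched protein)
8	9903986	9904242	257	MIR597	162217	LINC00599	0	LINC00599	1667	1113	1.50	0.0001	FALSE	Long intergenic non-protein-coding RNA
8	27604977	27605252	276	GULOP	15903	CLU	0	CLU	156	105	1.49	0.005	FALSE	Clusterin (AD-aggregate-enriched protein)
9	35657748	35658022	275	SIT1	6797	RMRP_1	0	RMRP_1	472	184	2.57	0.0001	FALSE	RNA component of mitochondrial RNA processing endoribonuclease
10	101799051	101799385	335	NPM3	15637	MGEA5	0	MGEA5	683	432	1.58	0.0001	FALSE	Hyaluronidase / OGA
11	35663281	35663611	331	TRIM44	0	KRT18P14	196637	TRIM44	1147	592	1.94	0.0001	FALSE	Tripartite motif containing 44
11	62841562	62841839	278	RP11-727F15.9	7518	WDR74	0	WDR74	304	149	2.04	0.0001	FALSE	WD repeat domain 74
11	65502716	65503064	349	AP000769.7	4310	MALAT1_1	0	MALAT1_1	30539	16494	1.85	0.0001	FALSE	Metastasis associated lung adenocarcinoma transcript 1
11	111911504	111911780	277	RPL37AP8	22029	CRYAB	0	CRYAB	228	216	1.06	NA	TRUE	Crystallin alpha beta (AD-aggregate-enriched protein)
11	123061064	123061339	276	RPL31P47	9662	HSPA8	0	HSPA8	871	1512	0.58	0.0001	FALSE	Heat shock protein family A member 8
12	110281619	110281909	291	ATP2A2	0	RN7SL769P	78542	ATP2A2	433	225	1.92	0.0001	FALSE	SERCA2 calcium transport ATPase
13	45975357	45975649	293	AL445232.1	60203	ZC3H13	0	ZC3H13	372	240	1.55	0.0001	FALSE	Zinc finger CCCH-type containing 13
14	20343094	20343370	277	SNORD126	16567	RPPH1	0	RPPH1	2313	634	3.65	0.0001	FALSE	Ribonuclease P RNA component H1
14	23321579	23321860	282	PABPN1	0	SLC22A17	24445	PABPN1	341	261	1.31	0.01	FALSE	Poly(A) binding protein nuclear 1
14	49586595	49586871	277	RNA5SP384	33846	RPS29	0	RPS29	22800	4958	4.60	0.0001	FALSE	Ribosomal protein, small subunit 29
14	49853648	49853923	276	RNU6-539P	13820	Metazoa_SRP_138	0	Metazoa_SRP_138	24010	7554	3.18	0.0001	FALSE	Cytoplasmic signal recognition particle RNA
14	102084750	102085033	284	RN7SL472P	7277	HSP90AA1	0	HSP90AA1	186	94	1.98	0.0001	FALSE	HSP90 family (AD-aggregate-enriched protein)
17	6452910	6453209	300	FAM64A	1440	PITPNM3	0	PITPNM3	671	520	1.29	0.004	FALSE	Phosphatidylinositol transfer protein membrane-associated 3
17	19187969	19188246	278	KYNUP1	18300	SNORD3A	0	SNORD3A	342	99	3.45	0.0001	FALSE	Small nucleolar RNA
17	44911190	44911459	270	AC015936.3	6643	GFAP	0	GFAP	7051	8989	0.78	0.0002	FALSE	Glial fibrillary acidic protein (AD-aggregate-enriched protein)
18	49814124	49814400	277	ACAA2	163	RP11-886H22.1	0	RP11-886H22.1	295	139	2.12	0.0001	FALSE	Transcribed processed pseudogene
19	13298568	13298866	299	CTC-250I14.1	139779	CACNA1A	0	CACNA1A	10268	5984	1.72	0.0001	FALSE	Calcium voltage-gated channel subunit alpha-1 A
19	36304598	36304871	274	CTD-3162L10.1	0	LINC00665	8195	CTD-3162L10.1	556	164	3.39	0.0001	FALSE	Uncharacterized locus
19	44907737	44908015	279	APOE	0	CTB-129P6.7	1359	APOE	1028	1003	1.02	NA	TRUE	Apolipoprotein E (AD-aggregate-enriched protein)
19	48645763	48646036	274	DBP	8324	CA11	0	CA11	407	573	0.71	0.0002	FALSE	Carbonic anhydrase 11
19	49107777	49108115	339	SNRNP70	0	LIN7B	6208	SNRNP70	2096	1398	1.50	0.0001	FALSE	Small nuclear ribonucleoprotein U1 subunit 70
20	23637606	23637888	283	CST9	31729	CST3	0	CST3	573	742	0.77	0.003	FALSE	Cystatin C
20	41533110	41533383	274	RP4-620E11.5	150002	CHD6	0	CHD6	1245	864	1.44	0.0001	FALSE	Chromodomain helicase DNA binding protein 6
21	8258828	8259116	289	RNA5-8S5	1894	FP671120.6	0	FP671120.6	1200	132	9.09	0.0001	FALSE	Uncharacterized transcript
21	8435771	8435981	211	FP236383.5	0	FP236383.1	96	FP236383.5	207	12	17.25	0.0001	FALSE	Uncharacterized transcript
21	26021821	26022101	281	LLPHP2	258487	APP	0	APP	1477	702	2.10	0.0001	FALSE	Amyloid precursor protein (AD-aggregate-enriched protein)
X	140784311	140784609	299	LINC00632	11631	CDR1	0	CDR1	36675	62951	0.58	0.0001	FALSE	Cerebellar degeneration related protein 1
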