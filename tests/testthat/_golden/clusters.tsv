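cluster_id	chrom	strand	summit	n_sites	cellA_total_1	cellA_total_2	cellA_4sU_1	cellA_4sU_2	cellA_FT_1	cellA_FT_2	cellB_total_1	cellB_total_2	cellB_4sU_1	cellB_4sU_2	cellB_FT_1	cellB_FT_2	cellC_total_1	cellC_total_2	cellC_4sU_1	cellC_4sU_2	cellC_FT_1	cellC_FT_2	total	gene_id	region_class	host_intron
PAS00001	chrS	+	4518	1	40	41	41	35	35	37	37	35	46	30	38	42	36	45	44	37	48	41	708	G0001	TPA	NA
PAS00002	chrS	+	5006	1	28	29	42	26	31	29	37	23	39	44	27	32	27	31	46	31	33	35	590	G0001	TPA	NA
PAS00003	chrS	+	6331	1	11	11	25	21	4	11	9	9	26	16	7	9	9	13	16	28	9	10	244	G0001	TPA	NA
PAS00004	chrS	+	14574	1	54	64	40	30	51	70	62	70	25	32	85	73	69	59	35	21	75	63	978	G0002	TPA	NA
PAS00005	chrS	-	15093	1	77	82	102	88	102	94	72	83	111	99	90	80	78	76	106	99	87	82	1608	G0003	TPA	NA
PAS00006	chrS	-	15703	1	30	36	55	70	24	12	31	35	73	58	20	20	21	32	68	69	20	24	698	G0004	TPA	NA
PAS00007	chrS	-	21585	1	24	16	5	10	30	24	25	35	10	12	24	32	25	38	7	9	22	25	373	G0005	TPA	NA
PAS00008	chrS	-	31910	1	103	85	146	160	89	86	103	105	130	141	88	97	104	115	146	148	93	108	2047	G0006	TPA	NA
PAS00009	chrS	-	33442	1	151	142	178	179	161	174	185	193	149	159	163	166	191	183	167	193	186	172	3092	G0006	TPA	NA
PAS00010	chrS	-	34052	1	139	132	128	121	114	115	131	127	125	127	122	151	124	152	124	123	117	148	2320	G0007	TPA	NA
PAS00011	chrS	-	38989	1	37	38	84	99	21	25	31	36	82	110	26	21	43	42	95	89	23	34	936	G0007	IPA	1
PAS00012	chrS	-	42664	1	3	4	20	20	2	3	3	5	15	18	1	3	5	7	13	7	1	2	132	G0008	TPA	NA
PAS00013	chrS	-	44568	1	11	11	25	26	7	3	7	8	22	27	5	5	6	9	25	20	3	5	225	G0008	TPA	NA
PAS00014	chrS	-	45129	1	11	8	15	17	7	9	10	6	18	14	9	12	11	17	24	26	9	6	229	G0008	TPA	NA
PAS00015	chrS	-	48137	1	0	1	2	10	0	0	0	4	3	9	1	0	3	4	13	6	1	1	58	G0008	IPA	1
PAS00016	chrS	+	50137	1	2	0	5	6	1	1	1	2	9	11	0	0	1	3	6	5	1	0	54	G0009	TPA	NA
PAS00017	chrS	+	53114	1	13	18	40	42	8	9	19	16	52	48	5	9	15	12	30	44	7	4	391	G0010	IPA	1
PAS00018	chrS	+	54018	1	50	35	65	59	38	37	48	42	62	66	39	38	54	38	60	60	38	22	851	G0010	TPA	NA
PAS00019	chrS	+	57538	1	17	21	72	72	11	13	24	27	67	72	7	19	28	21	78	68	10	11	638	G0011	IPA	1
PAS00020	chrS	+	64522	1	32	40	60	73	37	45	29	40	71	52	39	34	38	44	56	63	42	37	832	G0011	TPA	NA
PAS00021	chrS	-	65041	1	75	73	43	57	81	73	62	84	55	50	82	87	95	74	55	55	97	83	1281	G0012	TPA	NA
PAS00022	chrS	+	74583	1	60	62	43	43	72	80	76	66	40	47	70	64	38	37	44	39	33	45	959	G0013	TPA	NA
PAS00023	chrS	+	74971	1	44	22	31	28	26	30	30	26	18	26	31	35	13	20	34	24	10	14	462	G0013	TPA	NA
PAS00024	chrS	-	75490	1	25	27	66	70	18	22	27	24	56	45	23	22	36	30	70	69	18	26	674	G0014	TPA	NA
PAS00025	chrS	+	88158	1	109	124	102	99	126	124	120	115	93	99	117	118	137	154	100	108	113	137	2095	G0015	TPA	NA
PAS00026	chrS	-	88677	1	46	58	93	94	41	62	50	47	77	61	46	45	69	58	90	87	59	38	1121	G0016	TPA	NA
PAS00027	chrS	+	92960	1	172	181	48	55	198	205	188	207	51	51	211	227	194	194	44	59	211	225	2721	G0017	TPA	NA
PAS00028	chrS	+	93672	1	113	120	44	44	113	115	94	99	46	45	106	115	115	96	52	39	130	133	1619	G0017	TPA	NA
PAS00029	chrS	+	94282	1	39	28	32	42	31	22	27	28	28	42	17	35	15	15	23	43	17	9	493	G0018	TPA	NA
PAS00030	chrS	+	94892	1	112	119	24	30	116	112	99	121	23	28	129	116	106	122	29	34	145	141	1606	G0019	TPA	NA
PAS00031	chrS	+	95152	1	73	66	28	31	76	61	71	63	31	27	74	76	59	62	32	34	77	76	1017	G0019	TPA	NA
PAS00032	chrS	+	95762	1	47	48	25	31	59	47	39	38	24	30	51	39	60	42	23	24	43	31	701	G0019	TPA	NA
PAS00033	chrS	-	96281	1	48	46	89	75	32	42	45	51	82	99	37	46	50	38	88	98	46	37	1049	G0020	TPA	NA
PAS00034	chrS	+	101653	1	12	13	14	24	20	15	19	14	19	20	15	16	26	16	17	16	25	11	312	G0021	IPA	1
PAS00035	chrS	+	104119	1	91	99	28	43	100	103	109	84	34	28	117	105	93	96	36	38	115	124	1443	G0021	TPA	NA
PAS00036	chrS	+	106001	1	47	48	37	32	59	80	51	44	23	28	63	46	59	55	30	17	69	66	854	G0021	TPA	NA
PAS00037	chrS	-	106520	1	31	34	26	32	28	43	41	33	35	23	34	38	44	35	37	30	43	30	617	G0022	TPA	NA
PAS00038	chrS	-	107130	1	32	43	67	75	14	33	39	39	72	95	27	23	36	37	70	85	23	25	835	G0023	TPA	NA
PAS00039	chrS	-	108886	1	42	26	68	64	33	33	25	43	58	76	28	39	38	42	62	73	29	27	806	G0023	TPA	NA
PAS00040	chrS	-	110249	1	72	68	76	116	67	72	79	66	81	101	71	69	80	75	99	95	76	79	1442	G0023	TPA	NA
PAS00041	chrS	-	115157	1	9	9	18	18	4	1	6	3	16	14	6	9	6	6	22	27	5	4	183	G0024	TPA	NA
PAS00042	chrS	-	115607	1	38	33	78	72	18	14	26	18	58	77	18	23	31	33	52	63	19	21	692	G0024	TPA	NA
PAS00043	chrS	-	115817	1	48	36	78	80	37	41	46	52	59	59	44	37	50	49	70	67	34	55	942	G0024	TPA	NA
PAS00044	chrS	+	120577	1	45	52	61	60	42	49	46	42	52	59	52	44	45	45	84	73	41	46	938	G0025	IPA	1
PAS00045	chrS	+	125751	1	104	73	29	48	81	96	97	66	45	41	106	99	74	74	35	43	90	93	1294	G0025	TPA	NA
PAS00046	chrS	+	125975	1	60	90	58	55	74	84	71	84	51	60	75	94	78	85	52	49	94	74	1288	G0025	TPA	NA
PAS00047	chrS	+	127718	1	34	48	30	38	41	43	40	40	36	27	40	41	61	33	49	43	47	49	740	G0025	TPA	NA
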