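id	cellA_1	cellA_2	cellB_1	cellB_2	cellC_1	cellC_2	mean_cellA	mean_cellB	mean_cellC	F	p	q
PAS00001	-0.16709	0.15468	-0.32286	0.45785	0.13148	0.17548	-0.0062	0.06749	0.15348	0.10721	0.90163	0.97135
PAS00002	-0.37692	0.23204	-0.57771	-0.48694	-0.47317	0.20247	-0.07244	-0.53233	-0.13535	0.89291	0.4963	0.97135
PAS00003	-2.58197	-0.85822	-1.93996	-0.85744	-0.82393	-1.4578	-1.7201	-1.3987	-1.14087	0.22235	0.81275	0.97135
PAS00004	0.41165	1.29683	1.7182	1.16222	1.10544	1.61224	0.85424	1.44021	1.35884	0.89602	0.49534	0.97135
PAS00005	0.06117	0.16967	-0.3498	-0.33496	-0.27901	-0.2444	0.11542	-0.34238	-0.26171	54.33358	0.0044	0.20696
PAS00006	-1.13515	-2.46955	-1.91501	-1.56348	-1.75944	-1.49607	-1.80235	-1.73924	-1.62776	0.04752	0.95429	0.97135
PAS00007	2.64554	1.33732	1.2156	1.3873	1.65767	1.50106	1.99143	1.30145	1.57937	0.81917	0.52016	0.97135
PAS00008	-0.6529	-0.82113	-0.61016	-0.56717	-0.64469	-0.42716	-0.73702	-0.58867	-0.53593	1.68399	0.32335	0.97135
PAS00009	-0.08364	0.03365	0.08232	0.03461	0.16141	-0.1388	-0.025	0.05846	0.01131	0.19796	0.83032	0.97135
PAS00010	-0.10593	0.00114	-0.08229	0.22217	-0.07787	0.29433	-0.0524	0.06994	0.10823	0.34804	0.73126	0.97135
PAS00011	-1.93871	-1.91088	-1.70426	-2.41644	-2.04021	-1.36081	-1.92479	-2.06035	-1.70051	0.40877	0.69664	0.97135
PAS00012	-3.25923	-2.66142	-3.95085	-2.61147	-3.69105	-1.77868	-2.96033	-3.28116	-2.73486	0.15571	0.86231	0.97135
PAS00013	-1.77498	-3.03989	-2.1842	-2.4599	-3.05184	-1.97207	-2.40744	-2.32205	-2.51195	0.0382	0.96298	0.97135
PAS00014	-1.03811	-0.84284	-1.04704	-0.24989	-1.40882	-2.08762	-0.94048	-0.64847	-1.74822	3.4331	0.16767	0.97135
PAS00015	-9.66838	-11.87327	-1.62983	-11.79703	-3.69105	-2.55457	-10.77083	-6.71343	-3.12281	1.60415	0.33591	0.97135
PAS00016	-2.25807	-2.50744	-11.90004	-12.08646	-2.57591	-10.93743	-2.38275	-11.99325	-6.75667	3.96832	0.14367	0.97135
PAS00017	-2.26042	-2.14756	-3.42512	-2.44225	-2.09317	-3.43122	-2.20399	-2.93368	-2.76219	0.63084	0.59062	0.97135
PAS00018	-0.71323	-0.59864	-0.716	-0.82397	-0.65297	-1.41996	-0.65594	-0.76999	-1.03646	0.74647	0.54561	0.97135
PAS00019	-2.64906	-2.39474	-3.30553	-1.9494	-2.95719	-2.60036	-2.5219	-2.62746	-2.77878	0.09849	0.90901	0.97135
PAS00020	-0.63623	-0.62342	-0.91155	-0.64048	-0.40905	-0.74039	-0.62983	-0.77601	-0.57472	0.70792	0.55997	0.97135
PAS00021	0.97472	0.43144	0.52893	0.77151	0.82448	0.62105	0.70308	0.65022	0.72277	0.04272	0.95876	0.97135
PAS00022	0.8048	0.97014	0.76008	0.41785	-0.40905	0.23383	0.88747	0.58896	-0.08761	5.37021	0.10202	0.97135
PAS00023	-0.19257	0.17404	0.73695	0.40126	-1.75931	-0.75011	-0.00926	0.56911	-1.25471	8.2365	0.06047	0.94735
PAS00024	-1.81316	-1.59522	-1.33094	-1.05988	-1.95324	-1.3806	-1.70419	-1.19541	-1.66692	2.15007	0.26344	0.97135
PAS00025	0.36602	0.39935	0.28396	0.22573	0.18228	0.37053	0.38268	0.25485	0.27641	1.40726	0.3706	0.97135
PAS00026	-1.12039	-0.52586	-0.79043	-0.46641	-0.60323	-1.16757	-0.82312	-0.62842	-0.8854	0.27756	0.77518	0.97135
PAS00027	2.10551	1.97259	2.00138	2.12652	2.26756	1.95849	2.03905	2.06395	2.11302	0.13194	0.88121	0.97135
PAS00028	1.42187	1.46052	1.15708	1.32604	1.32785	1.79721	1.4412	1.24156	1.56253	1.25904	0.40087	0.97135
PAS00029	0.01537	-0.85829	-0.76705	-0.29056	-0.43008	-2.22863	-0.42146	-0.52881	-1.32936	0.699	0.56338	0.97135
PAS00030	2.33407	1.97489	2.4403	2.02298	2.32779	2.0794	2.15448	2.23164	2.20359	0.05017	0.95185	0.97135
PAS00031	1.50166	1.05099	1.20795	1.46541	1.27268	1.1878	1.27633	1.33668	1.23024	0.12362	0.88799	0.97135
PAS00032	1.29988	0.67486	1.04015	0.35094	0.90859	0.39659	0.98737	0.69554	0.65259	0.35305	0.72829	0.97135
PAS00033	-1.41449	-0.76195	-1.19529	-1.1333	-0.92987	-1.3778	-1.08822	-1.16429	-1.15384	0.03237	0.96848	0.97135
PAS00034	0.57566	-0.60347	-0.38822	-0.34942	0.56228	-0.51308	-0.0139	-0.36882	0.0246	0.22151	0.81334	0.97135
PAS00035	1.89758	1.3347	1.73559	1.87925	1.68146	1.7336	1.61614	1.80742	1.70753	0.32286	0.74646	0.97135
PAS00036	0.73432	1.39637	1.40638	0.68861	1.20752	1.98416	1.06535	1.0475	1.59584	0.7483	0.54495	0.97135
PAS00037	0.16807	0.50075	-0.08906	0.69676	0.22276	0.02739	0.33441	0.30385	0.12508	0.20021	0.82867	0.97135
PAS00038	-2.19737	-1.10985	-1.4622	-2.07372	-1.59965	-1.73804	-1.65361	-1.76796	-1.66885	0.02936	0.97135	0.97135
PAS00039	-0.98184	-0.88104	-1.0978	-0.99002	-1.09019	-1.40746	-0.93144	-1.04391	-1.24882	2.53786	0.22642	0.97135
PAS00040	-0.12066	-0.61352	-0.23734	-0.57722	-0.37546	-0.23867	-0.36709	-0.40728	-0.30706	0.08093	0.92421	0.97135
PAS00041	-2.1081	-4.09197	-1.46191	-0.66482	-2.13097	-2.72673	-3.10004	-1.06337	-2.42885	2.62405	0.21936	0.97135
PAS00042	-2.05416	-2.28784	-1.73516	-1.77066	-1.44643	-1.55745	-2.171	-1.75291	-1.50194	20.10205	0.0183	0.42999
PAS00043	-1.01473	-0.88982	-0.47043	-0.7007	-1.0358	-0.25732	-0.95227	-0.58556	-0.64656	0.68674	0.56812	0.97135
PAS00044	-0.47722	-0.21765	-0.04724	-0.45073	-1.02876	-0.63884	-0.34744	-0.24899	-0.8338	3.07803	0.18755	0.97135
PAS00045	1.54296	1.07448	1.18878	1.24421	1.36847	1.14024	1.30872	1.21649	1.25435	0.0939	0.91295	0.97135
PAS00046	0.41263	0.68545	0.50913	0.62013	0.86008	0.62211	0.54904	0.56463	0.74109	0.95227	0.47839	0.97135
PAS00047	0.5118	0.25284	0.10475	0.57507	-0.05416	0.21583	0.38232	0.33991	0.08084	0.88501	0.49877	0.97135
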