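taxon_id	synthExp1_T0	synthExp1_P_d25_r1	synthExp1_P_d25_r2	synthExp1_P_d50_r1	synthExp1_P_d50_r2	synthExp1_P_d75_r1	synthExp1_P_d75_r2	synthExp1_P_d100_r1	synthExp1_P_d100_r2	synthExp1_PV_d25_r1	synthExp1_PV_d25_r2	synthExp1_PV_d50_r1	synthExp1_PV_d50_r2	synthExp1_PV_d75_r1	synthExp1_PV_d75_r2	synthExp1_PV_d100_r1	synthExp1_PV_d100_r2
ASV001	9	9	3	8	7	5	9	5	7	7	6	4	3	6	6	6	13
ASV002	2	6	4	3	2	0	2	4	1	1	5	4	1	5	2	1	1
ASV003	28	25	25	26	29	35	39	18	34	19	19	22	15	19	22	29	34
ASV004	39	49	34	39	39	44	42	40	40	37	51	44	48	31	36	54	49
ASV005	1	0	2	2	1	0	0	2	3	3	0	1	2	1	1	0	1
ASV006	24	29	28	29	25	28	19	26	29	22	15	22	18	25	22	22	25
ASV007	524	225	217	245	255	299	320	323	345	145	145	191	216	263	255	318	322
ASV008	14	1	7	9	5	8	11	6	10	4	2	6	7	10	7	7	9
ASV009	3	9	9	7	7	1	7	9	6	3	4	3	8	6	6	8	11
ASV010	133	153	167	151	143	155	147	147	150	123	139	150	123	164	171	163	183
ASV011	56	34	39	41	35	49	36	51	49	36	30	40	38	36	39	39	54
ASV012	43	28	20	35	26	43	30	29	38	10	19	29	23	29	24	43	29
ASV013	12	9	14	7	10	12	9	11	10	17	9	10	13	11	5	12	8
ASV014	53	34	41	46	43	56	51	57	53	20	22	34	26	35	47	54	73
ASV015	6	6	5	9	9	2	6	11	5	3	5	4	2	3	8	5	7
ASV016	219	209	230	242	244	241	258	260	263	188	178	203	223	239	231	249	256
ASV017	31	31	25	21	24	25	26	18	15	15	17	19	15	17	18	26	27
ASV018	27	10	16	10	13	15	16	15	24	5	8	7	15	17	18	19	22
ASV019	11	10	9	6	8	10	7	14	14	1	6	6	2	13	5	15	9
ASV020	9	8	7	8	11	12	10	9	9	9	7	6	7	11	4	13	13
ASV021	59	140	124	112	113	90	82	88	95	179	174	143	116	110	106	119	91
ASV022	5	3	4	2	4	2	5	5	0	5	2	2	4	0	5	10	2
ASV023	81	121	97	104	82	99	109	94	95	102	96	112	124	80	113	99	102
ASV024	150	107	118	107	127	127	123	110	109	131	132	131	149	128	128	130	110
ASV025	4	10	2	6	8	5	3	3	5	3	5	5	3	8	3	7	2
ASV026	260	169	159	197	214	224	190	220	233	163	193	180	177	225	191	226	239
ASV027	172	161	161	178	194	146	170	146	171	137	118	146	147	146	162	134	153
ASV028	65	56	43	53	48	61	49	65	53	43	40	57	40	58	50	48	65
ASV029	165	115	117	115	129	129	123	150	146	101	117	112	107	105	113	151	132
ASV030	9	3	4	6	8	6	8	5	6	5	6	8	8	11	4	4	9
ASV031	2	2	6	11	3	2	8	10	7	4	2	6	8	3	5	6	7
ASV032	332	513	549	472	476	450	441	470	401	558	520	475	512	465	505	394	383
ASV033	3	3	5	3	8	2	9	4	7	3	3	5	3	3	7	5	4
ASV034	143	191	178	191	181	170	183	173	174	203	206	184	197	180	207	180	177
ASV035	88	58	68	74	64	77	76	76	79	48	66	69	61	84	60	81	68
ASV036	23	32	13	28	27	33	30	39	31	34	24	34	22	40	24	28	29
ASV037	312	555	572	522	515	451	449	400	396	733	744	635	637	548	518	405	408
ASV038	6	10	7	9	8	7	20	14	23	10	2	8	10	13	5	15	16
ASV039	47	26	34	27	30	37	43	39	31	38	22	38	34	28	30	43	32
ASV040	18	28	25	27	13	30	22	22	21	20	29	33	24	12	25	20	13
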