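sample_id	individual_id	sex	GRIA2_freq	GRIA2_cov	CDKN2A_freq	CDKN2A_cov	TET2_freq	TET2_cov	age_published	ci_low_published	ci_high_published	note
1	1	male	1.60	48420	2.04	22260	7.34	26496	13.34	8.87	17.81	
2a	2	female	1.59	24334	2.03	22716	11.80	16883	10.21	5.74	14.68	
2b	2	female	1.49	18436	2.06	29655	16.56	22792	6.55	2.08	11.02	
3	3	female	1.44	19076	1.67	43217	13.69	27572	6.68	2.21	11.15	
4	4	male	2.25	20035	2.76	17315	8.48	30640	18.98	14.51	23.45	
5	5	male	2.24	17826	2.62	21377	9.03	38823	17.99	13.52	22.46	
6	6	female	1.48	21270	1.88	14074	19.19	44816	4.00	0.00	8.47	
7a	7	male	1.50	13543	1.76	24649	10.33	24956	9.65	5.18	14.12	
7b	7	male	1.76	19994	1.91	25090	9.87	31872	11.98	7.51	16.45	
8	8	female	1.77	17805	1.99	18078	9.54	15539	12.58	8.11	17.05	
9	9	male	0.89	21703	1.34	14625	12.82	22757	2.95	0.00	7.42	suspected calf at sighting
10	10	male	1.95	22460	1.70	21824	12.60	30447	10.33	5.86	14.80	
11	11	male	1.98	15554	2.63	14938	15.62	19611	12.14	7.67	16.61	
12	12	male	1.72	16008	1.92	21130	10.78	27109	11.18	6.71	15.65	
13	13	male	0.66	22376	1.99	25506	11.31	17658	5.30	0.83	9.77	calf of pair 13/14
14	14	female	2.66	24223	4.64	31651	5.96	18329	30.40	25.93	34.87	mother of pair 13/14
15	15	male	2.29	24402	2.25	16600	5.59	29588	19.14	14.67	23.61	
16a	16	male	2.61	24452	2.57	28260	15.34	10249	15.53	11.06	20.00	
16b	16	male	1.91	11007	2.48	65940	11.41	37026	14.02	9.55	18.49	
17	17	male	1.50	15201	2.23	36385	10.78	32444	11.21	6.74	15.68	
18	18	female	1.07	14132	1.85	44358	11.53	45768	6.84	2.37	11.31	
19	19	male	1.52	15664	2.06	37197	10.46	62287	10.86	6.39	15.33	
20	20	male	1.82	12911	2.43	33380	12.37	32636	12.67	8.20	17.14	
21a	21	male	1.96	29249	2.28	29356	11.53	50290	13.41	8.94	17.88	
21b	21	male	1.14	17822	2.38	29959	10.38	29817	10.11	5.64	14.58	
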