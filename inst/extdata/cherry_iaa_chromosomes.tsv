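chromosome	subgenome	n_transcripts	n_from_pf	n_from_pa	n_shared	frac_higher_pf	frac_tie	frac_higher_pa
Pce_Sa_Chro1	a	10675	6162	3953	2934	0.12	0.07	0.81
Pce_Sa_Chro2	a	6511	3757	2301	1713	0.18	0.09	0.73
Pce_Sa_Chro3	a	5597	3248	2019	1491	0.17	0.07	0.76
Pce_Sa_Chro4	a	4969	2830	1743	1281	0.19	0.07	0.74
Pce_Sa_Chro5	a	4446	2575	1627	1242	0.15	0.05	0.80
Pce_Sa_Chro6	a	6963	4212	2555	1986	0.19	0.07	0.74
Pce_Sa_Chro7	a	5280	3025	1969	1418	0.21	0.07	0.72
Pce_Sa_Chro8	a	5257	3100	1860	1360	0.21	0.11	0.68
Pce_Sf_Chro1	f	10133	6345	3495	2835	0.56	0.09	0.35
Pce_Sf_Chro2	f	6254	3865	2056	1602	0.53	0.13	0.34
Pce_Sf_Chro3	f	5869	3686	1953	1564	0.61	0.09	0.30
Pce_Sf_Chro4	f	5362	3296	1820	1411	0.61	0.09	0.29
Pce_Sf_Chro5	f	4032	2511	1425	1172	0.64	0.07	0.29
Pce_Sf_Chro6	f	6968	4512	2441	1981	0.60	0.09	0.31
Pce_Sf_Chro7	f	5033	3201	1687	1312	0.60	0.09	0.31
Pce_Sf_Chro8	f	4925	3158	1566	1230	0.61	0.12	0.28
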