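roi_index	roi_name	network	x	y	z
1	LH_Vis_1	Vis	-0.00626	-0.0641	0.00879
2	LH_Vis_2	Vis	-0.01479	-0.06288	-0.00726
3	LH_Vis_3	Vis	-0.01921	-0.0592	0.01874
4	LH_Vis_4	Vis	-0.0281	-0.05855	0.00268
5	LH_Vis_5	Vis	-0.00983	-0.05402	0.03479
6	LH_Vis_6	Vis	-0.02949	-0.05033	0.02868
7	LH_Vis_7	Vis	-0.03929	-0.05022	0.01262
8	LH_Vis_8	Vis	-0.04645	-0.04533	-0.00344
9	LH_Vis_9	Vis	-0.01821	-0.0435	0.04474
10	LH_SomMot_1	SomMot	-0.00187	-0.04044	0.05085
11	LH_SomMot_2	SomMot	-0.04699	-0.03883	0.02256
12	LH_SomMot_3	SomMot	-0.03551	-0.03838	0.03862
13	LH_SomMot_4	SomMot	-0.05491	-0.03418	0.0065
14	LH_SomMot_5	SomMot	-0.02022	-0.02875	0.05468
15	LH_SomMot_6	SomMot	-0.05863	-0.0264	-0.00956
16	LH_SomMot_7	SomMot	-0.05008	-0.0257	0.0325
17	LH_SomMot_8	SomMot	-0.03547	-0.02468	0.04856
18	LH_DorsAttn_1	DorsAttn	-0.00597	-0.02221	0.06079
19	LH_DorsAttn_2	DorsAttn	-0.05928	-0.021	0.01644
20	LH_DorsAttn_3	DorsAttn	-0.06362	-0.01334	0.00038
21	LH_DorsAttn_4	DorsAttn	-0.04761	-0.01255	0.04244
22	LH_DorsAttn_5	DorsAttn	-0.02619	-0.01081	0.0585
23	LH_DorsAttn_6	DorsAttn	-0.05895	-0.00735	0.02638
24	LH_DorsAttn_7	DorsAttn	-0.00519	-0.00476	0.06462
25	LH_SalVentAttn_1	SalVentAttn	-0.03845	-0.00159	0.05238
26	LH_SalVentAttn_2	SalVentAttn	-0.06417	0.00063	0.01032
27	LH_SalVentAttn_3	SalVentAttn	-0.01818	0.00322	0.06232
28	LH_SalVentAttn_4	SalVentAttn	-0.05367	0.00497	0.03632
29	LH_SalVentAttn_5	SalVentAttn	-0.06408	0.00926	-0.00574
30	LH_SalVentAttn_6	SalVentAttn	-0.06019	0.01385	0.02026
31	LH_SalVentAttn_7	SalVentAttn	-0.0435	0.01388	0.04626
32	LH_Limbic_1	Limbic	-0.02825	0.01637	0.05621
33	LH_Limbic_2	Limbic	-0.01149	0.02212	0.06003
34	LH_Limbic_3	Limbic	-0.06071	0.02284	0.00421
35	LH_Limbic_4	Limbic	-0.05201	0.02465	0.03021
36	LH_Limbic_5	Limbic	-0.04042	0.0313	0.04015
37	LH_Cont_1	Cont	-0.02654	0.03181	0.05009
38	LH_Cont_2	Cont	-0.05319	0.03457	0.01415
39	LH_Cont_3	Cont	-0.00467	0.03601	0.05391
40	LH_Cont_4	Cont	-0.04927	0.04235	-0.00191
41	LH_Cont_5	Cont	-0.04238	0.043	0.02409
42	LH_Cont_6	Cont	-0.0162	0.04505	0.04397
43	LH_Default_1	Default	-0.0295	0.04687	0.03403
44	LH_Default_2	Default	-0.03874	0.05157	0.00803
45	LH_Default_3	Default	-0.03152	0.05628	-0.00803
46	LH_Default_4	Default	-0.02592	0.05683	0.01797
47	LH_Default_5	Default	-0.01232	0.05739	0.02791
48	LH_Default_6	Default	-0.01884	0.06218	0.00191
49	LH_Default_7	Default	-0.00497	0.06372	0.01185
50	RH_Vis_1	Vis	0.00772	-0.06453	-0.00115
51	RH_Vis_2	Vis	0.01583	-0.06125	0.01491
52	RH_Vis_3	Vis	0.02109	-0.06048	-0.01109
53	RH_Vis_4	Vis	0.00219	-0.06002	0.02485
54	RH_Vis_5	Vis	0.02931	-0.0578	0.00497
55	RH_Vis_6	Vis	0.02155	-0.05293	0.03097
56	RH_Vis_7	Vis	0.03488	-0.05066	0.02103
57	RH_Vis_8	Vis	0.04104	-0.05016	-0.00497
58	RH_Vis_9	Vis	0.00856	-0.04978	0.04091
59	RH_SomMot_1	SomMot	0.0468	-0.04372	0.01109
60	RH_SomMot_2	SomMot	0.03587	-0.03954	0.03709
61	RH_SomMot_3	SomMot	0.02231	-0.03893	0.04703
62	RH_SomMot_4	SomMot	0.04815	-0.0342	0.02715
63	RH_SomMot_5	SomMot	0.05591	-0.03313	0.00115
64	RH_SomMot_6	SomMot	0.00937	-0.02986	0.05697
65	RH_SomMot_7	SomMot	0.0577	-0.02448	0.01721
66	RH_SomMot_8	SomMot	0.02861	-0.02412	0.05315
67	RH_DorsAttn_1	DorsAttn	0.04299	-0.02259	0.04321
68	RH_DorsAttn_2	DorsAttn	0.06116	-0.02017	-0.00879
69	RH_DorsAttn_3	DorsAttn	0.05386	-0.01476	0.03326
70	RH_DorsAttn_4	DorsAttn	0.00952	-0.01242	0.06309
71	RH_DorsAttn_5	DorsAttn	0.06349	-0.01187	0.00726
72	RH_DorsAttn_6	DorsAttn	0.02508	-0.00916	0.05926
73	RH_DorsAttn_7	DorsAttn	0.04196	-0.00565	0.04932
74	RH_SalVentAttn_1	SalVentAttn	0.06059	-0.0031	0.02332
75	RH_SalVentAttn_2	SalVentAttn	0.06491	0.00205	-0.00268
76	RH_SalVentAttn_3	SalVentAttn	0.05153	0.00427	0.03938
77	RH_SalVentAttn_4	SalVentAttn	0.03314	0.00729	0.05544
78	RH_SalVentAttn_5	SalVentAttn	0.06274	0.01047	0.01338
79	RH_SalVentAttn_6	SalVentAttn	0.01761	0.0112	0.06156
80	RH_SalVentAttn_7	SalVentAttn	0.00106	0.01211	0.06385
81	RH_Limbic_1	Limbic	0.05538	0.01707	0.02944
82	RH_Limbic_2	Limbic	0.04214	0.01947	0.0455
83	RH_Limbic_3	Limbic	0.06024	0.02418	0.00344
84	RH_Limbic_4	Limbic	0.01266	0.02705	0.05774
85	RH_Limbic_5	Limbic	0.028	0.02787	0.05162
86	RH_Cont_1	Cont	0.05395	0.03057	0.0195
87	RH_Cont_2	Cont	0.04334	0.03289	0.03556
88	RH_Cont_3	Cont	0.05345	0.03642	-0.0065
89	RH_Cont_4	Cont	0.02698	0.04196	0.04168
90	RH_Cont_5	Cont	0.04783	0.04296	0.00956
91	RH_Cont_6	Cont	0.00967	0.04298	0.04779
92	RH_Default_1	Default	0.03872	0.04549	0.02562
93	RH_Default_2	Default	0.0379	0.05281	-0.00038
94	RH_Default_3	Default	0.00026	0.05284	0.03785
95	RH_Default_4	Default	0.01972	0.05319	0.03174
96	RH_Default_5	Default	0.02962	0.0557	0.01568
97	RH_Default_6	Default	0.02535	0.05896	-0.01032
98	RH_Default_7	Default	0.00846	0.06065	0.02179
99	RH_Default_8	Default	0.01742	0.06236	0.00574
100	RH_Vis_10	Vis	0.00363	0.06476	-0.00421
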