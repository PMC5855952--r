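position	ref	alt
1	0.53079	0.383019
2	0.753866	1.099731
3	0.259024	0.198446
4	1.127145	0.648851
5	0.588182	0.677604
6	0.978906	0.812959
7	1.262946	1.437903
8	2.01598	2.382178
9	1.626953	1.762286
10	2.454106	3.306008
11	0.748039	0.788141
12	0.835712	0.673014
13	2.300486	2.373303
14	0.599372	0.449235
15	0.640797	0.768597
16	0.596001	0.421623
17	1.137035	0.71746
18	0.795207	0.524819
19	2.281278	2.315281
20	1.713786	1.265882
21	1.77981	1.86271
22	1.157733	0.939948
23	1.359049	0.956634
24	0.748037	0.932421
25	0.834045	1.210243
26	0.67675	0.725798
27	0.205099	0.27229
28	0.924325	0.738794
29	0.921816	0.964891
30	2.468603	2.32837
31	1.812135	3.187206
32	0.554212	0.48606
33	1.552403	1.497113
34	0.733909	0.809074
35	1.146577	1.72406
36	0.552635	0.53642
37	1.137059	1.310948
38	1.041636	0.911395
39	0.852228	0.783887
40	1.377102	0.908622
41	0.921046	1.877564
42	1.989434	3.694199
43	2.431901	3.733471
44	0.434137	1.608621
45	2.208741	3.809152
46	2.412401	3.389334
47	0.57667	1.676058
48	1.046557	2.005254
49	0.911501	1.993453
50	2.365501	5.016271
51	2.050318	3.574535
52	1.168493	2.927292
53	3.100113	3.283267
54	0.623264	2.350747
55	0.521772	1.807762
56	2.493399	1.923823
57	1.294659	1.110956
58	1.494154	1.462039
59	1.164095	0.969848
60	0.500404	0.484453
61	4.348173	3.534532
62	1.306996	1.276071
63	0.310025	0.302057
64	1.058942	1.098553
65	0.576972	0.460437
66	0.531139	0.359594
67	3.41779	3.195321
68	4.422597	4.405051
69	0.618972	0.742613
70	1.290544	0.759114
71	0.333824	0.418852
72	1.139065	1.350037
73	0.410261	0.480032
74	2.392321	4.018633
75	0.59505	0.730605
76	1.664375	1.25055
77	0.390078	0.350287
78	3.679946	4.537363
79	0.99319	0.848998
80	1.098957	0.84216
81	0.780507	1.102976
82	2.67612	2.78022
83	0.524944	0.71889
84	1.925541	2.663839
85	3.10991	3.659679
86	2.225538	2.172536
87	0.337504	0.544411
88	1.283127	0.982393
89	1.009527	1.179517
90	0.981271	1.093927
91	0.424183	0.371667
92	1.675941	1.517549
93	2.941752	3.827121
94	2.287072	3.073831
95	0.732515	0.642583
96	0.916687	1.163602
97	0.904462	0.71484
98	2.375685	2.621293
99	1.237367	1.516816
100	1.50881	2.097768
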