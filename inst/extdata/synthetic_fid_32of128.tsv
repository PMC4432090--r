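# n_points=128
# dwell=0.00050000000000000001
# t0=0
# label=15N
# bf_mhz=60.810000000000002
index	real	imag	sampled
0	2.0075390212056727	-0.0074640464763445569	1
1	1.6904865071567186	-0.98250105034192592	1
2	0.93020912661204458	-1.6418852266729762	1
3	-0.0029300628713637747	-1.834189685428431	1
4	-0.89827398168789263	-1.5085440756078436	1
5	-1.4083054175464353	-0.80839970979081566	1
6	-1.5155489115984324	0.014013823680823663	1
7	-1.1889408560660752	0.68014001725149675	1
8	-0.59800733760650937	1.0737820283179418	1
9	0.016161451639697611	1.0825740626520381	1
10	0.45444136615442848	0.77041780768249468	1
11	0.64650409920209317	0.35693995768040515	1
12	0.58227349771960446	-0.010224010618015103	1
13	0.33781654465448829	-0.20846284051381006	1
14	0.11344042266851165	-0.17506378222327057	1
15	0.0017633711786037734	-0.014017338025001779	1
16	0.068891835625411027	0.14186994941471523	1
17	0.26378162830568014	0.15475730751068426	1
18	0.48434228742372548	-0.0021080772478392976	1
19	0.52570688893553907	-0.33146681760023378	1
20	0.36110792987207668	-0.65214899639413981	1
21	-0.010665755836415197	-0.8917485529724255	1
22	-0.51777046336695098	-0.87361426605629522	1
23	-0.97080518369912361	-0.53453802164528319	1
24	-1.2080244811156793	0.032036434506530737	1
25	-1.100503336096478	0.67765219988081504	1
26	-0.6585884761438634	1.184109415111293	1
27	0.039458518691108932	1.3811399464877772	1
28	0.74831141729085582	1.2060091681748186	1
29	1.2699950566291902	0.66820115329118768	1
30	1.4068324604583364	-0.052673947609004387	1
31	1.1834949483972534	-0.75122651021795439	1
32	0	0	0
33	0	0	0
34	0	0	0
35	0	0	0
36	0	0	0
37	0	0	0
38	0	0	0
39	0	0	0
40	0	0	0
41	0	0	0
42	0	0	0
43	0	0	0
44	0	0	0
45	0	0	0
46	0	0	0
47	0	0	0
48	0	0	0
49	0	0	0
50	0	0	0
51	0	0	0
52	0	0	0
53	0	0	0
54	0	0	0
55	0	0	0
56	0	0	0
57	0	0	0
58	0	0	0
59	0	0	0
60	0	0	0
61	0	0	0
62	0	0	0
63	0	0	0
64	0	0	0
65	0	0	0
66	0	0	0
67	0	0	0
68	0	0	0
69	0	0	0
70	0	0	0
71	0	0	0
72	0	0	0
73	0	0	0
74	0	0	0
75	0	0	0
76	0	0	0
77	0	0	0
78	0	0	0
79	0	0	0
80	0	0	0
81	0	0	0
82	0	0	0
83	0	0	0
84	0	0	0
85	0	0	0
86	0	0	0
87	0	0	0
88	0	0	0
89	0	0	0
90	0	0	0
91	0	0	0
92	0	0	0
93	0	0	0
94	0	0	0
95	0	0	0
96	0	0	0
97	0	0	0
98	0	0	0
99	0	0	0
100	0	0	0
101	0	0	0
102	0	0	0
103	0	0	0
104	0	0	0
105	0	0	0
106	0	0	0
107	0	0	0
108	0	0	0
109	0	0	0
110	0	0	0
111	0	0	0
112	0	0	0
113	0	0	0
114	0	0	0
115	0	0	0
116	0	0	0
117	0	0	0
118	0	0	0
119	0	0	0
120	0	0	0
121	0	0	0
122	0	0	0
123	0	0	0
124	0	0	0
125	0	0	0
126	0	0	0
127	0	0	0
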