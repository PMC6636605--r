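node_id	node_name	macro_region	hemisphere
1	SFG_L_1	SFG	L
2	SFG_R_1	SFG	R
3	SFG_L_2	SFG	L
4	SFG_R_2	SFG	R
5	SFG_L_3	SFG	L
6	SFG_R_3	SFG	R
7	SFG_L_4	SFG	L
8	SFG_R_4	SFG	R
9	SFG_L_5	SFG	L
10	SFG_R_5	SFG	R
11	SFG_L_6	SFG	L
12	SFG_R_6	SFG	R
13	SFG_L_7	SFG	L
14	SFG_R_7	SFG	R
15	MFG_L_1	MFG	L
16	MFG_R_1	MFG	R
17	MFG_L_2	MFG	L
18	MFG_R_2	MFG	R
19	MFG_L_3	MFG	L
20	MFG_R_3	MFG	R
21	MFG_L_4	MFG	L
22	MFG_R_4	MFG	R
23	MFG_L_5	MFG	L
24	MFG_R_5	MFG	R
25	MFG_L_6	MFG	L
26	MFG_R_6	MFG	R
27	MFG_L_7	MFG	L
28	MFG_R_7	MFG	R
29	IFG_L_1	IFG	L
30	IFG_R_1	IFG	R
31	IFG_L_2	IFG	L
32	IFG_R_2	IFG	R
33	IFG_L_3	IFG	L
34	IFG_R_3	IFG	R
35	IFG_L_4	IFG	L
36	IFG_R_4	IFG	R
37	IFG_L_5	IFG	L
38	IFG_R_5	IFG	R
39	IFG_L_6	IFG	L
40	IFG_R_6	IFG	R
41	OrG_L_1	OrG	L
42	OrG_R_1	OrG	R
43	OrG_L_2	OrG	L
44	OrG_R_2	OrG	R
45	OrG_L_3	OrG	L
46	OrG_R_3	OrG	R
47	OrG_L_4	OrG	L
48	OrG_R_4	OrG	R
49	OrG_L_5	OrG	L
50	OrG_R_5	OrG	R
51	OrG_L_6	OrG	L
52	OrG_R_6	OrG	R
53	PrG_L_1	PrG	L
54	PrG_R_1	PrG	R
55	PrG_L_2	PrG	L
56	PrG_R_2	PrG	R
57	PrG_L_3	PrG	L
58	PrG_R_3	PrG	R
59	PrG_L_4	PrG	L
60	PrG_R_4	PrG	R
61	PrG_L_5	PrG	L
62	PrG_R_5	PrG	R
63	PrG_L_6	PrG	L
64	PrG_R_6	PrG	R
65	PCL_L_1	PCL	L
66	PCL_R_1	PCL	R
67	PCL_L_2	PCL	L
68	PCL_R_2	PCL	R
69	STG_L_1	STG	L
70	STG_R_1	STG	R
71	STG_L_2	STG	L
72	STG_R_2	STG	R
73	STG_L_3	STG	L
74	STG_R_3	STG	R
75	STG_L_4	STG	L
76	STG_R_4	STG	R
77	STG_L_5	STG	L
78	STG_R_5	STG	R
79	STG_L_6	STG	L
80	STG_R_6	STG	R
81	MTG_L_1	MTG	L
82	MTG_R_1	MTG	R
83	MTG_L_2	MTG	L
84	MTG_R_2	MTG	R
85	MTG_L_3	MTG	L
86	MTG_R_3	MTG	R
87	MTG_L_4	MTG	L
88	MTG_R_4	MTG	R
89	ITG_L_1	ITG	L
90	ITG_R_1	ITG	R
91	ITG_L_2	ITG	L
92	ITG_R_2	ITG	R
93	ITG_L_3	ITG	L
94	ITG_R_3	ITG	R
95	ITG_L_4	ITG	L
96	ITG_R_4	ITG	R
97	ITG_L_5	ITG	L
98	ITG_R_5	ITG	R
99	ITG_L_6	ITG	L
100	ITG_R_6	ITG	R
101	ITG_L_7	ITG	L
102	ITG_R_7	ITG	R
103	FuG_L_1	FuG	L
104	FuG_R_1	FuG	R
105	FuG_L_2	FuG	L
106	FuG_R_2	FuG	R
107	FuG_L_3	FuG	L
108	FuG_R_3	FuG	R
109	PhG_L_1	PhG	L
110	PhG_R_1	PhG	R
111	PhG_L_2	PhG	L
112	PhG_R_2	PhG	R
113	PhG_L_3	PhG	L
114	PhG_R_3	PhG	R
115	PhG_L_4	PhG	L
116	PhG_R_4	PhG	R
117	PhG_L_5	PhG	L
118	PhG_R_5	PhG	R
119	PhG_L_6	PhG	L
120	PhG_R_6	PhG	R
121	pSTS_L_1	pSTS	L
122	pSTS_R_1	pSTS	R
123	pSTS_L_2	pSTS	L
124	pSTS_R_2	pSTS	R
125	SPL_L_1	SPL	L
126	SPL_R_1	SPL	R
127	SPL_L_2	SPL	L
128	SPL_R_2	SPL	R
129	SPL_L_3	SPL	L
130	SPL_R_3	SPL	R
131	SPL_L_4	SPL	L
132	SPL_R_4	SPL	R
133	SPL_L_5	SPL	L
134	SPL_R_5	SPL	R
135	IPL_L_1	IPL	L
136	IPL_R_1	IPL	R
137	IPL_L_2	IPL	L
138	IPL_R_2	IPL	R
139	IPL_L_3	IPL	L
140	IPL_R_3	IPL	R
141	IPL_L_4	IPL	L
142	IPL_R_4	IPL	R
143	IPL_L_5	IPL	L
144	IPL_R_5	IPL	R
145	IPL_L_6	IPL	L
146	IPL_R_6	IPL	R
147	Pcun_L_1	Pcun	L
148	Pcun_R_1	Pcun	R
149	Pcun_L_2	Pcun	L
150	Pcun_R_2	Pcun	R
151	Pcun_L_3	Pcun	L
152	Pcun_R_3	Pcun	R
153	Pcun_L_4	Pcun	L
154	Pcun_R_4	Pcun	R
155	PoG_L_1	PoG	L
156	PoG_R_1	PoG	R
157	PoG_L_2	PoG	L
158	PoG_R_2	PoG	R
159	PoG_L_3	PoG	L
160	PoG_R_3	PoG	R
161	PoG_L_4	PoG	L
162	PoG_R_4	PoG	R
163	INS_L_1	INS	L
164	INS_R_1	INS	R
165	INS_L_2	INS	L
166	INS_R_2	INS	R
167	INS_L_3	INS	L
168	INS_R_3	INS	R
169	INS_L_4	INS	L
170	INS_R_4	INS	R
171	INS_L_5	INS	L
172	INS_R_5	INS	R
173	INS_L_6	INS	L
174	INS_R_6	INS	R
175	CG_L_1	CG	L
176	CG_R_1	CG	R
177	CG_L_2	CG	L
178	CG_R_2	CG	R
179	CG_L_3	CG	L
180	CG_R_3	CG	R
181	CG_L_4	CG	L
182	CG_R_4	CG	R
183	CG_L_5	CG	L
184	CG_R_5	CG	R
185	CG_L_6	CG	L
186	CG_R_6	CG	R
187	CG_L_7	CG	L
188	CG_R_7	CG	R
189	MVOcC_L_1	MVOcC	L
190	MVOcC_R_1	MVOcC	R
191	MVOcC_L_2	MVOcC	L
192	MVOcC_R_2	MVOcC	R
193	MVOcC_L_3	MVOcC	L
194	MVOcC_R_3	MVOcC	R
195	MVOcC_L_4	MVOcC	L
196	MVOcC_R_4	MVOcC	R
197	MVOcC_L_5	MVOcC	L
198	MVOcC_R_5	MVOcC	R
199	LOcC_L_1	LOcC	L
200	LOcC_R_1	LOcC	R
201	LOcC_L_2	LOcC	L
202	LOcC_R_2	LOcC	R
203	LOcC_L_3	LOcC	L
204	LOcC_R_3	LOcC	R
205	LOcC_L_4	LOcC	L
206	LOcC_R_4	LOcC	R
207	LOcC_L_5	LOcC	L
208	LOcC_R_5	LOcC	R
209	LOcC_L_6	LOcC	L
210	LOcC_R_6	LOcC	R
211	Amyg_L_1	Amyg	L
212	Amyg_R_1	Amyg	R
213	Amyg_L_2	Amyg	L
214	Amyg_R_2	Amyg	R
215	Hipp_L_1	Hipp	L
216	Hipp_R_1	Hipp	R
217	Hipp_L_2	Hipp	L
218	Hipp_R_2	Hipp	R
219	BG_L_1	BG	L
220	BG_R_1	BG	R
221	BG_L_2	BG	L
222	BG_R_2	BG	R
223	BG_L_3	BG	L
224	BG_R_3	BG	R
225	BG_L_4	BG	L
226	BG_R_4	BG	R
227	BG_L_5	BG	L
228	BG_R_5	BG	R
229	BG_L_6	BG	L
230	BG_R_6	BG	R
231	Tha_L_1	Tha	L
232	Tha_R_1	Tha	R
233	Tha_L_2	Tha	L
234	Tha_R_2	Tha	R
235	Tha_L_3	Tha	L
236	Tha_R_3	Tha	R
237	Tha_L_4	Tha	L
238	Tha_R_4	Tha	R
239	Tha_L_5	Tha	L
240	Tha_R_5	Tha	R
241	Tha_L_6	Tha	L
242	Tha_R_6	Tha	R
243	Tha_L_7	Tha	L
244	Tha_R_7	Tha	R
245	Tha_L_8	Tha	L
246	Tha_R_8	Tha	R
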