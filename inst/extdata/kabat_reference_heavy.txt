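# Synthetic consensus-like sheep VH reference profile (Kabat-annotated).
# Two columns: Kabat code <TAB> reference residue. '#' lines are comments.
# FR1 1-30, CDR-H1 31-35, FR2 36-49, CDR-H2 50-65, FR3 66-94 (incl. 82A-82C),
# CDR-H3 95-102, FR4 103-113.
1	E
2	V
3	Q
4	L
5	L
6	E
7	S
8	G
9	G
10	G
11	L
12	V
13	Q
14	P
15	G
16	G
17	S
18	L
19	R
20	L
21	S
22	C
23	A
24	A
25	S
26	G
27	F
28	T
29	F
30	S
31	S
32	Y
33	A
34	M
35	S
36	W
37	V
38	R
39	Q
40	A
41	P
42	G
43	K
44	G
45	L
46	E
47	W
48	V
49	S
50	A
51	I
52	S
53	G
54	S
55	G
56	G
57	S
58	T
59	Y
60	Y
61	A
62	D
63	S
64	V
65	K
66	G
67	R
68	F
69	T
70	I
71	S
72	R
73	D
74	N
75	S
76	K
77	N
78	T
79	L
80	Y
81	L
82	Q
82A	M
82B	N
82C	S
83	L
84	R
85	A
86	E
87	D
88	T
89	A
90	V
91	Y
92	Y
93	C
94	A
95	R
96	D
97	Y
98	Y
99	G
100	S
101	S
102	Y
103	W
104	G
105	Q
106	G
107	T
108	L
109	V
110	T
111	V
112	S
113	S
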