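bit	element	min_count
0	H	4
1	H	8
2	H	16
3	H	32
4	Li	1
5	Li	2
6	B	1
7	B	2
8	B	4
9	C	2
10	C	4
11	C	8
12	C	16
13	C	32
14	N	1
15	N	2
16	N	4
17	N	8
18	O	1
19	O	2
20	O	4
21	O	8
22	O	16
23	F	1
24	F	2
25	F	4
26	Na	1
27	Na	2
28	Si	1
29	Si	2
30	P	1
31	P	2
32	P	4
33	S	1
34	S	2
35	S	4
36	S	8
37	Cl	1
38	Cl	2
39	Cl	4
40	Cl	8
41	K	1
42	K	2
43	Br	1
44	Br	2
45	Br	4
46	I	1
47	I	2
48	I	4
49	Be	1
50	Mg	1
51	Al	1
52	Ca	1
53	Sc	1
54	Ti	1
55	V	1
56	Cr	1
57	Mn	1
58	Fe	1
59	Co	1
60	Ni	1
61	Cu	1
62	Zn	1
63	Ga	1
64	Ge	1
65	As	1
66	Se	1
67	Kr	1
68	Rb	1
69	Sr	1
70	Y	1
71	Zr	1
72	Nb	1
73	Mo	1
74	Tc	1
75	Ru	1
76	Rh	1
77	Pd	1
78	Ag	1
79	Cd	1
80	In	1
81	Sn	1
82	Sb	1
83	Te	1
84	Xe	1
85	Cs	1
86	Ba	1
87	Lu	1
88	Hf	1
89	Ta	1
90	W	1
91	Re	1
92	Os	1
93	Ir	1
94	Pt	1
95	Au	1
96	Hg	1
97	Tl	1
98	Pb	1
99	Bi	1
100	La	1
101	Ce	1
102	Pr	1
103	Nd	1
104	Pm	1
105	Sm	1
106	Eu	1
107	Gd	1
108	Tb	1
109	Dy	1
110	Ho	1
111	Er	1
112	Tm	1
113	Yb	1
114	U	1
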