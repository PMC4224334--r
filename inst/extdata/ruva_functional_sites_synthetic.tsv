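# SYNTHETIC stand-in fixture: 51 RuvA amino acid sites important for folding,
# multimerization or DNA binding. Position 118 (DNA binding; the E. coli
# Lys-118 junction contact) is from the published narrative; all other
# positions are constructed placeholders laid out over the three structural
# domains and must be replaced by a curated literature synthesis for real
# analyses.
position	role	source
8	folding	synthetic placeholder
11	folding	synthetic placeholder
14	DNA-binding	synthetic placeholder
17	multimerization	synthetic placeholder
20	DNA-binding	synthetic placeholder
23	folding	synthetic placeholder
27	multimerization	synthetic placeholder
30	DNA-binding	synthetic placeholder
33	folding	synthetic placeholder
36	multimerization	synthetic placeholder
39	DNA-binding	synthetic placeholder
43	folding	synthetic placeholder
46	multimerization	synthetic placeholder
49	DNA-binding	synthetic placeholder
52	folding	synthetic placeholder
55	multimerization	synthetic placeholder
58	DNA-binding	synthetic placeholder
61	folding	synthetic placeholder
66	multimerization	synthetic placeholder
69	DNA-binding	synthetic placeholder
72	folding	synthetic placeholder
75	multimerization	synthetic placeholder
78	DNA-binding	synthetic placeholder
82	folding	synthetic placeholder
85	multimerization	synthetic placeholder
88	DNA-binding	synthetic placeholder
91	folding	synthetic placeholder
95	multimerization	synthetic placeholder
98	DNA-binding	synthetic placeholder
101	folding	synthetic placeholder
104	multimerization	synthetic placeholder
108	DNA-binding	synthetic placeholder
111	folding	synthetic placeholder
114	multimerization	synthetic placeholder
118	DNA-binding	Lys-118 nonpolar junction contact (narrative)
121	folding	synthetic placeholder
124	multimerization	synthetic placeholder
128	DNA-binding	synthetic placeholder
133	folding	synthetic placeholder
137	multimerization	synthetic placeholder
141	DNA-binding	synthetic placeholder
145	folding	synthetic placeholder
149	multimerization	synthetic placeholder
153	DNA-binding	synthetic placeholder
157	folding	synthetic placeholder
161	multimerization	synthetic placeholder
168	DNA-binding	synthetic placeholder
172	folding	synthetic placeholder
181	multimerization	synthetic placeholder
188	DNA-binding	synthetic placeholder
196	folding	synthetic placeholder
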