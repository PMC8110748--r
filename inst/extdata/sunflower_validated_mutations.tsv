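gene	dna_change	position	ref	alt	f_score	zygosity	category	aa_ref	aa_position	aa_alt	severity_reported
HaLHY	C3741T	3741	C	T	146.0	hom	missense	S	333	F	PSM
HaLUX3	A89G	89	A	G	87.2	het	missense	D	15	G	PSM
HaELF4_2	G391A	391	G	A	38.1	het	missense	D	122	N	NSM
HaFT4	C792T	792	C	T	30.3	het	missense	P	76	S	PSM
HaELF3_3	C1187T	1187	C	T	24.2	het	missense	S	73	F	PSM
HaPIN3/4/7_1	C956T	956	C	T	19.1	hom	missense	P	305	S	PSM
HaLUX2	C227T	227	C	T	17.8	het	truncation	Q	68	*	PSM
HaGA2OX	T1816C	1816	T	C	17.0	het	missense	S	188	P	PSM
HaPIN3/4/7_4	A3786G	3786	A	G	16.1	het	missense	Y	588	C	PSM
HaLUX3	C389T	389	C	T	14.9	het	missense	S	115	F	PSM
HaLUX3	A530G	530	A	G	14.6	het	missense	E	162	G	PSM
HaPIN3/4/7_4	G1347A	1347	G	A	14.3	het	missense	G	281	D	PSM
HaLUX2	C813T	813	C	T	11.8	hom	missense	P	263	L	PSM
HaPIN3/4/7_3	G2147T	2147	G	T	10.7	het	missense	G	581	C	PSM
HaLUX2	G542A	542	G	A	8.5	het	missense	A	173	T	NSM
HaPIN3/4/7_2	C1467T	1467	C	T	7.7	het	missense	R	214	W	PSM
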