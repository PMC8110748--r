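fragment	canonical_intron	canonical_missense	canonical_silent	canonical_splice	canonical_truncation	noncanonical_intron	noncanonical_missense	noncanonical_silent	noncanonical_splice	tilled_length	tilled_exon	tilled_intron	total	total_canonical	total_noncanonical	total_intron	total_exon
HaBFT	1	2	9	0	1	12	23	32	2	1971	522	1449	82	13	69	13	69
HaCenH3_1_1	6	0	1	0	0	10	2	0	0	1479	222	1257	19	7	12	16	3
HaCenH3_1_2	5	3	0	0	0	26	2	14	0	1358	207	1151	50	8	42	31	19
HaCenH3_2	3	2	0	0	0	26	7	9	0	2025	351	1674	47	5	42	29	18
HaELF3_3	6	6	3	0	0	22	10	8	0	3303	1899	1404	55	15	40	28	27
HaELF4_1	0	1	10	0	0	0	1	7	0	2870	378	2492	19	11	8	0	19
HaELF4_2	0	3	6	0	0	0	6	5	0	1034	390	644	20	9	11	0	20
HaELF4_3	0	1	3	0	0	0	0	0	0	1295	312	983	4	4	0	0	4
HaELF4_4	0	1	2	0	0	0	5	13	0	1957	309	1648	21	3	18	0	21
HaELF4_5	7	3	1	0	1	15	7	6	0	1474	351	1123	40	12	28	22	18
HaFT1	7	3	2	0	0	43	5	2	0	3423	576	2847	62	12	50	50	12
HaFT2	11	3	2	1	0	57	6	18	1	3131	528	2603	99	17	82	68	31
HaFT4	10	2	2	0	0	7	6	4	0	2532	525	2007	31	14	17	17	14
HaGA2OX	7	3	5	0	0	9	12	13	0	3256	975	2281	49	15	34	16	33
HaLHY	8	16	6	0	0	23	47	34	1	4838	1926	2912	135	30	105	31	104
HaLUX2	0	5	2	0	1	0	3	5	0	1000	903	97	16	8	8	0	16
HaLUX3	0	4	1	0	0	0	5	7	0	1145	870	275	17	5	12	0	17
HaPIN3/4/7_1	4	7	7	0	0	4	13	20	0	2982	1830	1152	55	18	37	8	47
HaPIN3/4/7_2	8	7	6	0	1	41	34	7	0	5113	1830	3283	104	22	82	49	55
HaPIN3/4/7_3	2	2	6	0	0	4	3	7	0	3252	1851	1401	24	10	14	6	18
HaPIN3/4/7_4	21	16	11	0	1	45	28	26	0	4759	1860	2899	148	49	99	66	82
HaTFL1_1	1	0	0	0	0	6	6	5	0	1805	263	1542	18	1	17	7	11
HaTFL1_2	4	1	0	0	0	2	0	1	0	2093	259	1834	8	5	3	6	2
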