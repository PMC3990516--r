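strain	age	chrom	expressed	up	down
wholeX	5	1	1141	0	7
wholeX	7	1	1215	17	40
wholeX	5	2	1345	1	12
wholeX	7	2	1475	12	60
wholeX	5	3	869	0	9
wholeX	7	3	927	8	45
wholeX	5	4	1029	0	8
wholeX	7	4	1113	6	45
wholeX	5	5	1033	1	9
wholeX	7	5	1125	15	43
wholeX	5	6	811	0	5
wholeX	7	6	895	15	41
wholeX	5	7	1016	1	13
wholeX	7	7	1103	14	41
wholeX	5	8	819	0	9
wholeX	7	8	889	14	38
wholeX	5	9	886	0	10
wholeX	7	9	971	11	46
wholeX	5	10	789	0	5
wholeX	7	10	850	13	25
wholeX	5	11	1363	1	12
wholeX	7	11	1447	10	52
wholeX	5	12	661	1	2
wholeX	7	12	716	6	23
wholeX	5	13	659	0	4
wholeX	7	13	704	16	22
wholeX	5	14	600	1	8
wholeX	7	14	641	6	37
wholeX	5	15	668	0	5
wholeX	7	15	721	11	18
wholeX	5	16	585	0	4
wholeX	7	16	634	1	26
wholeX	5	17	750	0	5
wholeX	7	17	811	8	23
wholeX	5	18	513	1	4
wholeX	7	18	547	12	23
wholeX	5	19	572	0	6
wholeX	7	19	634	5	20
wholeX	5	X	437	15	43
wholeX	7	X	472	28	70
distalX	5	1	1169	0	2
distalX	7	1	1250	15	47
distalX	5	2	1383	0	2
distalX	7	2	1503	11	60
distalX	5	3	890	1	1
distalX	7	3	944	15	36
distalX	5	4	1058	1	0
distalX	7	4	1154	5	40
distalX	5	5	1070	0	1
distalX	7	5	1155	9	45
distalX	5	6	838	0	1
distalX	7	6	918	15	45
distalX	5	7	1038	0	1
distalX	7	7	1135	14	38
distalX	5	8	847	0	0
distalX	7	8	917	15	35
distalX	5	9	918	1	0
distalX	7	9	996	10	49
distalX	5	10	804	0	0
distalX	7	10	861	11	27
distalX	5	11	1400	0	8
distalX	7	11	1493	19	70
distalX	5	12	678	0	2
distalX	7	12	731	7	25
distalX	5	13	679	0	3
distalX	7	13	718	15	30
distalX	5	14	612	0	0
distalX	7	14	661	5	32
distalX	5	15	686	0	0
distalX	7	15	740	6	21
distalX	5	16	597	0	0
distalX	7	16	655	1	28
distalX	5	17	775	1	0
distalX	7	17	836	8	20
distalX	5	18	529	2	0
distalX	7	18	552	6	22
distalX	5	19	602	1	0
distalX	7	19	652	2	27
distalX	5	proX	297	0	0
distalX	7	proX	323	4	21
distalX	5	disX	239	6	23
distalX	7	disX	255	16	44
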