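chrom	distanceCM	rateCMperMb	linkageCM
1	260	2.2	246
1A	180	2.4	206
2	290	1.8	316
3	210	1.8	225
4	160	2.3	167
4A	40	1.9	80
5	200	3.1	170
6	90	2.4	121
7	100	2.5	122
8	100	3.1	96
9	60	2.2	96
10	80	3.7	94
11	70	3.2	81
12	60	2.7	84
13	110	5.9	87
14	80	4.6	87
15	110	7.4	59
17	60	4.8	73
18	100	7.6	79
19	30	2.5	58
20	60	3.8	53
21	60	7.4	48
22	60	10.5	53
23	60	7.6	49
24	60	7.5	50
25	60	21.4	47
26	70	9.1	46
27	90	16.1	73
28	60	9.7	48
LGE22	60	27.9	53
Z	180	3.0	161
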