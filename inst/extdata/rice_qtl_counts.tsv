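chromosome	YLD	GW	HD	PH	TN
1	26	48	18	44	13
2	17	38	18	15	5
3	20	59	54	28	8
4	12	22	11	20	3
5	9	42	12	12	8
6	12	26	40	9	10
7	16	12	43	20	10
8	15	15	24	17	3
9	7	16	5	4	2
10	3	13	10	6	2
11	8	12	6	5	3
12	3	10	2	7	2
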