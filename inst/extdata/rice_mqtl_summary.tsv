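trait	chromosome	mqtl_id	flank_left	flank_right	position_cm	ci_cm	start_mb	end_mb	n_qtls	n_studies	n_populations	n_genes
GW	1	MQTL-GW1	RM3233	C52458s	32.27	3.73	5.05	6.58	7	5	5	175
GW	1	MQTL-GW2	RM3366	RM1349	103.77	2.67	24.26	25.07	5	3	4	108
GW	1	MQTL-GW3	RM1095	RM5914	129.95	2.01	30.92	31.50	2	2	2	77
GW	1	MQTL-GW4	RM3447	RM6618	144.29	3.07	35.25	37.01	7	4	4	221
GW	1	MQTL-GW5	RM8049	RM6831	178.53	3.35	42.07	43.17	2	2	2	165
GW	2	MQTL-GW6	RM452	G243A	49.85	5.97	9.56	11.75	10	6	7	165
GW	2	MQTL-GW7	RM7245	RM221	110.97	6.42	26.44	27.60	2	2	2	147
GW	2	MQTL-GW8	R2216	RM5993	124.58	2.79	28.41	29.70	4	3	3	171
GW	2	MQTL-GW9	RM8030	RM5958	140.25	1.06	32.48	32.83	2	2	2	48
GW	3	MQTL-GW10	R134	RM4512	46.9	5.21	9.49	11.30	3	3	3	271
GW	3	MQTL-GW11	RM6931	C11260S	70.66	2.07	14.98	15.47	7	4	4	37
GW	3	MQTL-GW12	S1466	RM6425	92.12	3.12	22.98	23.82	3	2	2	59
GW	3	MQTL-GW13	R2462	R635	136.1	0.8	30.10	30.38	2	2	2	237
GW	4	MQTL-GW14	RM5687	RM6314	34.77	15.5	15.74	18.44	3	2	2	136
GW	4	MQTL-GW15	R278	RM2848	74.44	0.4	23.43	24.49	5	4	4	158
GW	4	MQTL-GW16	R2737	RM5503	97.98	4.41	29.15	30.17	10	4	4	139
GW	5	MQTL-GW17	S2309	S2136	11.47	3.27	0.94	1.29	2	2	2	47
GW	5	MQTL-GW18	RM7349	RM3322	30.98	2.01	3.24	4.26	5	3	3	106
GW	5	MQTL-GW19	S21985S	E2801S	60.92	6.32	14.54	16.95	3	2	2	181
GW	5	MQTL-GW20	RM6282	E10316S	80.4	5.48	20.24	21.13	6	3	3	103
GW	5	MQTL-GW21	RG470	RM3620	102.11	3.59	23.48	25.20	2	2	2	204
GW	6	MQTL-GW22	R10069S	RM3330	59.06	2.81	10.46	11.06	6	5	5	47
GW	7	MQTL-GW23	RM5100	RM5752	10.75	2.19	2.21	2.56	2	2	2	23
GW	7	MQTL-GW24	R646	RM1048	64.86	11.35	16.96	20.16	6	5	5	261
GW	8	MQTL-GW25	S12665S	C1251S	58.89	5.8	5.80	8.15	3	2	2	139
GW	8	MQTL-GW26	S3680	RM8264	80.09	6.78	18.25	19.83	3	3	3	128
GW	9	MQTL-GW27	C1454	C397	78.8	7.33	9.63	12.28	3	3	3	169
GW	9	MQTL-GW28	S4677S	RM7039	92.53	1.96	13.62	14.68	4	3	3	107
GW	10	MQTL-GW29	RM6144	RM3229	40.14	6.1	15.60	16.69	4	3	3	101
GW	10	MQTL-GW30	RM7300	RM147	61.67	2.23	19.93	20.94	4	2	2	140
GW	11	MQTL-GW31	RM1812	RM1124	22.71	7.29	2.40	3.85	3	2	2	155
GW	11	MQTL-GW32	S20163S	RM3701	38.66	11.35	5.37	8.10	2	2	2	244
GW	11	MQTL-GW33	R10329S	RM4746	69.14	0.86	16.04	16.57	5	2	2	29
GW	12	MQTL-GW34	RM3326	C11001SA	77.56	6.92	21.74	22.45	4	3	3	35
HD	1	MQTL-HD1	C12072S	C52458	31.9	4.1	5.51	6.58	2	2	2	128
HD	2	MQTL-HD2	E50474S	RM3505	32.82	6.81	5.64	7.54	3	2	2	212
HD	2	MQTL-HD3	C1236	R418	117.41	8.35	27.36	28.94	2	2	2	180
HD	2	MQTL-HD4	R685	RG256	134.61	1.2	31.26	33.93	4	4	4	363
HD	3	MQTL-HD5	C51477S	RM601	35.78	1.85	1.03	1.66	11	8	11	79
HD	3	MQTL-HD6	C68	RM6496	44.5	2.18	9.31	10.14	8	5	5	130
HD	3	MQTL-HD7	RM5626	RM7097	104.68	10.87	24.86	26.87	3	2	2	196
HD	3	MQTL-HD8	R2404	RM3867	142.69	0.59	31.38	31.74	13	8	11	61
HD	4	MQTL-HD9	R2811	RM4835	12.69	8.62	2.08	6.98	3	3	3	225
HD	4	MQTL-HD10	RM6314	S10644	42.81	10.76	18.44	19.04	2	2	2	52
HD	5	MQTL-HD11	S2467	RM3969	69.48	7.81	17.14	18.93	3	2	2	169
HD	5	MQTL-HD12	E60663S	R1714	99.43	26.84	21.14	27.80	2	2	2	874
HD	6	MQTL-HD13	C425A	RM521	8.38	2.6	1.64	2.36	3	3	3	112
HD	6	MQTL-HD14	RM6836	RM8238	54.49	0.14	9.30	9.45	4	3	3	13
HD	7	MQTL-HD15	RM214	RM7183	50.66	0.3	12.78	14.95	5	5	5	97
HD	7	MQTL-HD16	RM432	RM7087	65.58	0.3	18.95	19.35	4	4	4	29
HD	7	MQTL-HD17	C50171S	RM478	88.85	4.48	24.62	25.94	2	2	2	158
HD	7	MQTL-HD18	S11279	C924	116.89	0.05	29.01	29.21	6	4	5	31
HD	8	MQTL-HD19	E60560S	RZ562	51.31	1.95	4.17	5.42	5	4	4	112
HD	8	MQTL-HD20	RM3181	RM7027	65.87	9.82	7.55	15.84	2	2	2	439
HD	8	MQTL-HD21	RM8264	RM4668	84.77	1.18	19.83	20.53	4	4	4	59
HD	10	MQTL-HD22	RM496	RM590	68.87	2	22.43	23.04	5	4	4	82
HD	11	MQTL-HD23	S20162S	RM6894	36.24	3.59	5.37	5.91	4	4	4	60
PH	1	MQTL-PH1	RM5359	RM6630	41.15	6.65	7.17	8.36	5	3	3	152
PH	1	MQTL-PH2	C1905	E3004S	72.04	5.86	12.64	15.16	2	2	2	184
PH	1	MQTL-PH3	R2374	RM3475	107.61	2.84	25.06	26.04	2	2	2	99
PH	1	MQTL-PH4	RM5461	V176	115.3	1.4	26.90	27.11	3	2	2	25
PH	1	MQTL-PH5	C1459	RM3411	129.19	2.12	30.53	31.31	5	5	5	117
PH	1	MQTL-PH6	RM8278	RM6618	146.15	0.07	36.62	37.01	4	3	3	36
PH	1	MQTL-PH7	RM3442	RM8235	150.9	3.2	38.20	38.43	2	2	2	40
PH	1	MQTL-PH8	RM8049	E60152S	176.16	6.28	42.07	42.68	2	2	2	95
PH	2	MQTL-PH9	RM6853	RM452	44.24	5.59	8.95	9.56	2	2	2	39
PH	2	MQTL-PH10	S13984	RM599	107.09	5.32	25.62	27.10	3	3	3	186
PH	3	MQTL-PH11	RM6013	R2247	9.16	3.62	1.66	2.48	2	2	2	125
PH	3	MQTL-PH12	RM7249	RM6080	61.25	2.77	12.90	13.93	4	4	4	82
PH	3	MQTL-PH13	C831	S851	147.69	0.65	32.92	33.03	8	7	7	25
PH	4	MQTL-PH14	S10983	RM6314	36.41	1.18	16.77	18.44	4	2	2	82
PH	4	MQTL-PH15	C2043	RM3839	67.33	11.14	20.56	23.90	2	2	2	428
PH	4	MQTL-PH16	G379B	RZ879B	108.46	4.29	30.63	33.12	2	2	2	359
PH	5	MQTL-PH17	R1436	RZ649	72.97	4.71	18.25	19.54	3	3	3	127
PH	5	MQTL-PH18	RM3476	R3802S	101.7	2.48	23.84	24.60	3	2	2	107
PH	6	MQTL-PH19	RM5371	RM6782	98.23	0.64	25.82	26.04	5	4	4	26
PH	7	MQTL-PH20	RM214	RM7183	50.65	0.3	12.78	14.95	3	2	2	97
PH	7	MQTL-PH21	RM1135	RM5405	60.21	4.05	16.93	18.58	2	2	2	120
PH	7	MQTL-PH22	RM3555	RM5720	107.11	1.89	27.89	28.66	3	3	3	123
PH	8	MQTL-PH23	E20920S	C1107	60.6	5.56	6.03	8.68	7	5	6	164
PH	8	MQTL-PH24	RM7356	RM210	92.21	1.7	21.28	22.47	2	2	2	101
PH	9	MQTL-PH25	RM1189	RM7048	103.29	3.16	16.27	16.93	4	3	3	80
PH	10	MQTL-PH26	RM3311	RM8201	22.39	6.64	10.62	13.76	2	2	2	204
PH	10	MQTL-PH27	RM5304	S11014	45.45	8.06	16.34	17.98	3	3	3	164
PH	12	MQTL-PH28	C11001SA	R10289S	82.7	7.6	22.45	23.06	2	2	2	60
YLD	1	MQTL-YLD1	RG246	T96	21.31	8.24	3.50	4.44	2	2	2	122
YLD	1	MQTL-YLD2	C1905	C45	71.67	5.43	12.64	14.79	3	3	3	154
YLD	1	MQTL-YLD3	RM5919	RM3475	106.72	6.72	24.73	26.04	3	3	3	146
YLD	1	MQTL-YLD4	RM7414	RM3336	120.29	5.52	27.17	28.61	2	2	2	192
YLD	1	MQTL-YLD5	RM8061	RM6950	139.01	0.03	34.12	34.50	6	5	5	44
YLD	2	MQTL-YLD6	RM7413	RM8254	69.29	11.41	18.45	19.74	2	2	2	132
YLD	2	MQTL-YLD7	RM6933	RM3857	128.89	8.94	29.30	31.84	5	3	3	264
YLD	3	MQTL-YLD8	S13802	C2184A	44.79	3.92	9.24	10.39	2	2	2	183
YLD	3	MQTL-YLD9	C1186	G144	68.71	2.3	14.55	15.33	2	2	2	71
YLD	3	MQTL-YLD10	RM5864	RZ403	90.64	3	22.39	23.08	3	3	3	49
YLD	3	MQTL-YLD11	S10209	S11669	127.52	3.48	27.82	29.55	3	3	3	205
YLD	4	MQTL-YLD12	E30341S	RM471	32.96	8.12	16.28	18.82	2	2	2	152
YLD	4	MQTL-YLD13	RM3337	RM3839	69.02	7.93	21.73	23.90	2	2	2	310
YLD	6	MQTL-YLD14	E4392S	RM439	109.26	4.78	27.37	29.62	3	3	3	275
YLD	7	MQTL-YLD15	RM432	RM2966	66.59	4.89	18.95	19.73	3	3	3	65
YLD	8	MQTL-YLD16	E31128S	E2623S	70.14	5.57	11.58	17.51	3	3	3	258
YLD	8	MQTL-YLD17	G1073A	RG1	89.53	4.71	20.66	21.64	2	2	2	93
YLD	9	MQTL-YLD18	C397	S1824	85.91	4.14	12.28	13.63	2	2	2	98
YLD	11	MQTL-YLD19	S10207	R120	59.93	8.03	9.06	14.95	3	3	3	247
TN	1	MQTL-TN1	RM522	C52458	31.76	6.52	5.24	6.58	3	2	2	158
TN	1	MQTL-TN2	RM3614	S10712	127.12	2.46	29.82	31.36	3	3	3	247
TN	2	MQTL-TN3	C41	RM6617	98.74	1.17	24.52	24.76	4	4	4	28
TN	3	MQTL-TN4	RM1022	C63	39.95	5.93	7.23	9.31	5	5	5	257
TN	3	MQTL-TN5	C60318S	RM6425	87.26	12.69	16.78	23.82	2	2	2	475
TN	4	MQTL-TN6	S733	R738	90.92	5.95	27.86	28.90	2	2	2	119
TN	6	MQTL-TN7	RM253	RG213	27.32	2.97	5.42	6.28	2	2	2	100
TN	7	MQTL-TN8	RM432	RM2966	66.38	4.44	18.95	19.73	3	2	2	65
TN	8	MQTL-TN9	RM5767	RM1578	84.18	10.44	18.81	20.97	3	3	3	182
TN	9	MQTL-TN10	RM6543	C11503S	115.41	11.29	17.75	19.88	2	2	2	317
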