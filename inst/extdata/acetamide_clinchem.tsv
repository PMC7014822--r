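endpoint	series	dose	n	mean	sd
ast	expA_males_d8	0	6	76.67	3.88
ast	expA_males_d8	30	6	66.17	3.92
ast	expA_males_d8	100	6	69.67	1.84
ast	expA_males_d8	300	6	78.67	7.02
ast	expA_males_d8	1000	6	167.83	25.70
ast	males_d8	0	6	79.17	2.30
ast	males_d8	300	6	73.83	4.81
ast	males_d8	500	6	77.00	1.44
ast	males_d8	750	6	78.00	2.21
ast	males_d8	1000	6	80.67	4.45
ast	males_d8	1500	6	99.67	4.70
ast	males_d29	0	6	74.67	4.36
ast	males_d29	300	6	74.50	5.25
ast	males_d29	500	6	77.33	5.45
ast	males_d29	750	6	63.33	3.78
ast	males_d29	1000	6	93.00	8.72
ast	males_d29	1500	6	96.67	14.79
ast	females_d8	0	6	83.17	3.50
ast	females_d8	300	6	90.83	1.83
ast	females_d8	500	6	94.33	9.05
ast	females_d8	750	6	88.00	3.70
ast	females_d8	1000	6	101.00	6.85
ast	females_d8	1500	6	95.67	2.82
ast	females_d29	0	6	80.50	5.18
ast	females_d29	300	6	79.17	4.71
ast	females_d29	500	6	87.00	9.37
ast	females_d29	750	6	101.17	16.68
ast	females_d29	1000	6	93.67	6.23
ast	females_d29	1500	6	136.83	30.32
alt	expA_males_d8	0	6	57.00	4.46
alt	expA_males_d8	30	6	56.67	3.84
alt	expA_males_d8	100	6	52.83	4.19
alt	expA_males_d8	300	6	58.83	4.45
alt	expA_males_d8	1000	6	114.67	12.94
alt	males_d8	0	6	42.83	2.23
alt	males_d8	300	6	43.00	5.47
alt	males_d8	500	6	47.50	2.70
alt	males_d8	750	6	52.67	3.30
alt	males_d8	1000	6	55.00	6.77
alt	males_d8	1500	6	55.67	5.71
alt	males_d29	0	6	44.00	2.41
alt	males_d29	300	6	43.33	1.58
alt	males_d29	500	6	47.50	2.26
alt	males_d29	750	6	41.33	2.29
alt	males_d29	1000	6	55.17	6.33
alt	males_d29	1500	6	63.33	8.77
alt	females_d8	0	6	40.67	1.38
alt	females_d8	300	6	40.67	2.63
alt	females_d8	500	6	41.67	2.56
alt	females_d8	750	6	43.83	2.33
alt	females_d8	1000	6	51.17	2.56
alt	females_d8	1500	6	55.33	4.32
alt	females_d29	0	6	41.67	3.68
alt	females_d29	300	6	36.83	2.02
alt	females_d29	500	6	38.00	2.52
alt	females_d29	750	6	44.00	2.46
alt	females_d29	1000	6	47.83	3.77
alt	females_d29	1500	6	86.67	31.79
bilirubin	males_d8	0	6	2.94	0.18
bilirubin	males_d8	300	6	2.92	0.24
bilirubin	males_d8	500	6	3.18	0.14
bilirubin	males_d8	750	6	2.92	0.25
bilirubin	males_d8	1000	6	2.73	0.39
bilirubin	males_d8	1500	6	2.99	0.23
bilirubin	males_d29	0	6	2.24	0.27
bilirubin	males_d29	300	6	2.25	0.28
bilirubin	males_d29	500	6	2.88	0.38
bilirubin	males_d29	750	6	2.89	0.30
bilirubin	males_d29	1000	6	3.03	0.34
bilirubin	males_d29	1500	6	3.62	0.85
bilirubin	females_d8	0	6	2.80	0.14
bilirubin	females_d8	300	6	3.25	0.49
bilirubin	females_d8	500	6	3.49	0.29
bilirubin	females_d8	750	6	3.16	0.31
bilirubin	females_d8	1000	6	2.90	0.37
bilirubin	females_d8	1500	6	2.91	0.22
bilirubin	females_d29	0	6	2.55	0.18
bilirubin	females_d29	300	6	3.04	0.33
bilirubin	females_d29	500	6	3.27	0.47
bilirubin	females_d29	750	6	3.59	0.48
bilirubin	females_d29	1000	6	3.61	0.22
bilirubin	females_d29	1500	6	4.88	1.00
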