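series	direction	dose	count
expA_males_d8	up	30	0
expA_males_d8	up	100	0
expA_males_d8	up	300	1
expA_males_d8	up	1000	1717
expA_males_d8	down	30	0
expA_males_d8	down	100	0
expA_males_d8	down	300	0
expA_males_d8	down	1000	968
males_d8	up	300	0
males_d8	up	500	0
males_d8	up	750	0
males_d8	up	1000	0
males_d8	up	1500	129
males_d8	down	300	0
males_d8	down	500	1
males_d8	down	750	0
males_d8	down	1000	0
males_d8	down	1500	4
males_d29	up	300	1
males_d29	up	500	16
males_d29	up	750	22
males_d29	up	1000	223
males_d29	up	1500	941
males_d29	down	300	1
males_d29	down	500	2
males_d29	down	750	12
males_d29	down	1000	37
males_d29	down	1500	418
females_d8	up	300	0
females_d8	up	500	6
females_d8	up	750	146
females_d8	up	1000	167
females_d8	up	1500	926
females_d8	down	300	1
females_d8	down	500	1
females_d8	down	750	7
females_d8	down	1000	9
females_d8	down	1500	80
females_d29	up	300	0
females_d29	up	500	52
females_d29	up	750	109
females_d29	up	1000	352
females_d29	up	1500	1202
females_d29	down	300	0
females_d29	down	500	6
females_d29	down	750	48
females_d29	down	1000	109
females_d29	down	1500	478
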