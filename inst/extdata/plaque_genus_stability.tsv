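taxon	individual	mean	cv
Cor	A	17.4	48
Cor	B	13.9	56
Cor	D	20.4	34
Cor	E	7.8	70
Cor	H	14.3	35
Cor	J	7.7	41
Cor	K	6.1	58
Cor	R	17.2	50
Nei	A	9.5	54
Nei	B	1.3	169
Nei	D	6.8	80
Nei	E	1.2	190
Nei	H	8.8	46
Nei	J	30.2	36
Nei	K	24.2	78
Nei	R	0.8	71
Rot	A	1.9	85
Rot	B	9.4	65
Rot	D	18.8	60
Rot	E	14.4	77
Rot	H	5.9	35
Rot	J	5.8	46
Rot	K	10.4	71
Rot	R	11.8	48
Cap	A	20.9	25
Cap	B	11.3	25
Cap	D	7.7	52
Cap	E	2.9	64
Cap	H	9.1	37
Cap	J	11.8	36
Cap	K	6.8	40
Cap	R	6.4	68
Act	A	7.7	49
Act	B	11.1	26
Act	D	10.9	54
Act	E	8.2	30
Act	H	6	58
Act	J	4.8	87
Act	K	3.9	57
Act	R	19.8	32
Str	A	7.7	38
Str	B	13	51
Str	D	8.5	63
Str	E	8.3	22
Str	H	8.8	35
Str	J	3.5	25
Str	K	6.1	57
Str	R	15.3	30
Fus	A	7.4	57
Fus	B	9.1	101
Fus	D	6.6	76
Fus	E	8.1	56
Fus	H	9.6	34
Fus	J	4.9	66
Fus	K	8.9	63
Fus	R	6.1	75
Vei	A	3.3	120
Vei	B	7.9	51
Vei	D	2.5	62
Vei	E	7.6	94
Vei	H	5.2	44
Vei	J	0.7	118
Vei	K	3.6	87
Vei	R	10.7	39
Pre	A	1.4	66
Pre	B	2.5	94
Pre	D	0.4	120
Pre	E	19.9	38
Pre	H	2.8	82
Pre	J	0.6	167
Pre	K	8.4	88
Pre	R	1.6	120
Lep	A	8.5	46
Lep	B	2.6	39
Lep	D	5.2	78
Lep	E	6.7	66
Lep	H	4.9	36
Lep	J	6.8	66
Lep	K	1.9	75
Lep	R	0.9	133
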