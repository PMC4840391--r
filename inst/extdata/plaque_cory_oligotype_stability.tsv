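taxon	individual	mean	cv
Cor_01	A	1.4	42
Cor_01	B	52.7	15
Cor_01	D	52.2	25
Cor_01	E	35.1	46
Cor_01	H	78.6	8
Cor_01	J	15.3	56
Cor_01	K	28.7	49
Cor_01	R	52.2	21
Cor_02	A	41.5	34
Cor_02	B	0.4	138
Cor_02	D	1.1	70
Cor_02	E	0.6	124
Cor_02	H	0.2	124
Cor_02	J	35.4	33
Cor_02	K	0.5	98
Cor_02	R	0	283
Cor_03	A	2.6	68
Cor_03	B	2.8	64
Cor_03	D	6.2	59
Cor_03	E	24.6	47
Cor_03	H	1.2	120
Cor_03	J	27.4	63
Cor_03	K	39	59
Cor_03	R	11.3	58
Cor_04	A	29.2	55
Cor_04	B	8.6	67
Cor_04	D	0.4	173
Cor_04	E	4.6	107
Cor_04	H	0.3	264
Cor_04	R	18.2	40
Cor_05	A	0.3	194
Cor_05	B	20.8	40
Cor_05	D	11.8	104
Cor_05	E	4.4	158
Cor_05	H	5.1	81
Cor_05	J	1.1	141
Cor_05	K	3.8	74
Cor_05	R	6	45
Cor_06	A	0	186
Cor_06	B	0.1	200
Cor_06	D	10.8	32
Cor_06	E	11.1	34
Cor_06	H	0.5	108
Cor_06	J	0.2	186
Cor_06	K	1.1	102
Cor_06	R	0.2	119
Cor_10	E	0	283
Cor_10	H	3.7	130
Cor_10	J	13.4	72
Cor_10	K	0.1	283
Cor_12	E	0	283
Cor_12	H	0.1	217
Cor_12	K	19.4	56
Cor_12	R	0.1	200
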