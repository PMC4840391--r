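taxon	overall_mean	overall_cv
Cor_01	39.5	64
Cor_02	9.9	178
Cor_03	14.4	119
Cor_04	7.7	157
Cor_05	6.7	129
Cor_06	3	166
Cor_10	2.2	266
Cor_12	2.4	303
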