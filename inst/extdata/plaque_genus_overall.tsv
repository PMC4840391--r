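taxon	overall_mean	overall_cv	mean_cv
Cor	13.1	60	49
Nei	10.3	126	90
Rot	9.8	84	61
Cap	9.6	64	43
Act	9	68	49
Str	8.9	58	40
Fus	7.6	68	66
Vei	5.2	92	77
Pre	4.7	155	97
Lep	4.7	83	67
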