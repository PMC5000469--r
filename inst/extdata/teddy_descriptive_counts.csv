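variable,level,n_active,n_withdrawn
overall,all,2994,763
country,finland,747,140
country,germany,106,36
country,sweden,1052,231
country,us,1089,356
child_sex,male,1538,352
child_sex,female,1456,411
smoked,yes,296,171
smoked,no,2602,510
smoked,(missing),96,82
alcohol_3rd_trimester,monthly_1_2,474,72
alcohol_3rd_trimester,monthly_3_plus,105,13
alcohol_3rd_trimester,none,2359,609
alcohol_3rd_trimester,(missing),56,69
worked_all_trimesters,yes,1418,251
worked_all_trimesters,no,1426,417
worked_all_trimesters,(missing),150,95
dad_participation,yes,2813,624
dad_participation,no,181,139
risk_perception,accurate,1809,355
risk_perception,underestimate,1132,343
risk_perception,(missing),53,65
anxiety_score,(missing),46,63
missing_count,le_1,2944,695
missing_count,gt_1,50,68
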