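rule_id	direction	rule
rule_1	increasing	maternal_age < 27.5 AND country != finland
rule_2	increasing	smoked = yes AND risk_perception != accurate AND anxiety_score > 45
rule_3	increasing	anxiety_score > 45 AND dad_participation = no
rule_4	increasing	maternal_age < 27.5 AND risk_perception != accurate AND alcohol_3rd_trimester in {none, monthly_1_2}
rule_5	decreasing	worked_all_trimesters = yes AND smoked = no
rule_6	decreasing	country != finland AND alcohol_3rd_trimester != none AND negative_life_events < 2
rule_7	decreasing	smoked = no AND anxiety_score < 45 AND missing_count <= 1
rule_8	decreasing	maternal_age > 27.5 AND smoked = no AND missing_count <= 1
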