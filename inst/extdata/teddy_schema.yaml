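outcome: withdrawn
variables:
- name: country
  kind: categorical
  levels:
  - finland
  - germany
  - sweden
  - us
- name: child_sex
  kind: categorical
  levels:
  - male
  - female
- name: maternal_age
  kind: continuous
  min: 15.0
  max: 50.0
- name: smoked
  kind: categorical
  levels:
  - 'no'
  - 'yes'
- name: alcohol_3rd_trimester
  kind: categorical
  levels:
  - none
  - monthly_1_2
  - monthly_3_plus
- name: worked_all_trimesters
  kind: categorical
  levels:
  - 'no'
  - 'yes'
- name: dad_participation
  kind: categorical
  levels:
  - 'no'
  - 'yes'
- name: risk_perception
  kind: categorical
  levels:
  - underestimate
  - accurate
- name: anxiety_score
  kind: continuous
  min: 20.0
  max: 80.0
- name: negative_life_events
  kind: count
  min: 0.0
- name: missing_count
  kind: count
  min: 0.0
  derived: yes
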