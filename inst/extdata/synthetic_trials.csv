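"study_id","treated_events","treated_total","control_events","control_total"
"study_01",13,60,10,60
"study_02",28,80,20,80
"study_03",41,100,20,100
"study_04",41,120,36,120
"study_05",47,150,35,150
"study_06",25,70,17,70
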