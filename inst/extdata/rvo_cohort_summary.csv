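variable,type,g1_a,g1_b,g1_n,g2_a,g2_b,g2_n
sex_men_women,binary,19,24,43,17,13,30
eye_right_left,binary,22,21,43,15,15,30
age_years,continuous,55.42,12.95,43,44.74,15.37,30
diabetes_yes_no,binary,2,41,43,0,30,30
hypertension_yes_no,binary,15,28,43,0,30,30
hyperlipidaemia_yes_no,binary,6,37,43,0,30,30
atherosclerosis_yes_no,binary,11,32,43,1,29,30
bcva_initial,continuous,0.43,0.29,43,0.93,0.10,30
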