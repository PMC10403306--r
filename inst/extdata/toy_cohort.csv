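subject_id,a,age0,sex,apoe4,education,sbp_1,sbp_2,sbp_3,bmi_1,bmi_2,bmi_3,comorb_1,comorb_2,comorb_3,dementia_year,death_year,admin_end
s1,1,60,1,0,2,135,137,,26,26.5,27,0,0,1,2,3,3
s2,0,65,0,1,3,142,140,141,24,24,24,0,1,1,,2,3
s3,1,58,0,0,4,128,129,130,28,28,28,0,0,0,,,3
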