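band,age_min,age_max,hr_high,hr_low,rr_high,temp_high,temp_low,wbc_high,wbc_low
infant,0,1,180,90,34,38.5,36,17.5,5
toddler_preschool,1,6,140,NA,22,38.5,36,15.5,6
school_age,6,13,130,NA,18,38.5,36,13.5,4.5
adolescent,13,18.01,110,NA,14,38.5,36,11,4.5
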