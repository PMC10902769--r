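sex,age_lo,age_hi,a_weight,b_height,c_const,unit
female,18,30,0.0546,0,2.33,MJ_per_day
female,30,60,0.0407,0,2.90,MJ_per_day
female,60,70,0.0429,0,2.39,MJ_per_day
female,70,110,0.0417,0,2.41,MJ_per_day
male,18,30,0.0669,0,2.28,MJ_per_day
male,30,60,0.0592,0,2.48,MJ_per_day
male,60,70,0.0543,0,2.37,MJ_per_day
male,70,110,0.0573,0,2.01,MJ_per_day
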