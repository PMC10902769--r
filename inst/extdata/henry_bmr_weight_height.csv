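sex,age_lo,age_hi,a_weight,b_height,c_const,unit
female,18,30,0.0433,2.57,-1.180,MJ_per_day
female,30,60,0.0342,2.10,-0.0486,MJ_per_day
female,60,110,0.0356,1.76,0.0448,MJ_per_day
male,18,30,0.0600,1.31,0.473,MJ_per_day
male,30,60,0.0476,2.26,-0.574,MJ_per_day
male,60,110,0.0478,2.26,-1.070,MJ_per_day
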