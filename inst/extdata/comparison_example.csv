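nutrient,median_24hr,median_generic,pct_diff_printed,effect_r,effect_label
energy_kcal,1569.9,1715.3,9.3,0.107,small
protein_g,65.4,72.7,11.2,0.032,small
protein_pcttei,16.6,16.8,0.8,0.060,small
carbohydrate_g,192,202.8,5.6,0.162,small
carbohydrate_pcttei,44.5,45.5,2.3,0.113,small
sugar_g,71.8,84.8,18.1,0.263,small
sugar_pcttei,16.6,18.6,12.2,0.249,small
fiber_g,17.2,16.7,-3.4,0.093,small
fat_g,61.6,63.1,2.4,0.011,small
fat_pcttei,34.7,33.8,-2.5,0.169,small
satfat_g,22,25.1,14.2,0.202,small
satfat_pcttei,12.3,13.5,9.8,0.220,small
mufa_g,22.1,22.7,2.7,0.004,small
mufa_pcttei,12.3,12.1,-1.5,0.076,small
pufa_g,7.6,11.1,46.7,0.598,large
pufa_pcttei,4.2,5.9,41,0.723,large
vitamin_d_ug,2.2,2.3,7.6,0.113,small
folate_ug,215.1,198.1,-7.9,0.334,moderate
vitamin_c_mg,72.3,67.1,-7.2,0.244,small
calcium_mg,686,796.4,16.1,0.250,small
iron_mg,9.9,9.9,0,0.119,small
potassium_mg,2865.5,2716.2,-5.2,0.204,small
sodium_mg,1685.5,2161,28.2,0.398,moderate
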