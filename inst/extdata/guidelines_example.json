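{
  "comment": "Example guideline configuration. Cut points are documented defaults drawn from common European adult recommendations; edit to match the guideline set in force for your cohort.",
  "guidelines": [
    {"nutrient": "protein_g", "unit": "g_per_kg_bw", "cut_points": [0.8, 2.0], "labels": ["low", "adequate", "high"]},
    {"nutrient": "carbohydrate_g", "unit": "percent_tei", "cut_points": [45, 60], "labels": ["low", "adequate", "high"]},
    {"nutrient": "fat_g", "unit": "percent_tei", "cut_points": [20, 35], "labels": ["low", "adequate", "high"]},
    {"nutrient": "mufa_g", "unit": "percent_tei", "cut_points": [10, 20], "labels": ["low", "adequate", "high"]},
    {"nutrient": "pufa_g", "unit": "percent_tei", "cut_points": [5, 10], "labels": ["low", "adequate", "high"]},
    {"nutrient": "satfat_g", "unit": "percent_tei", "cut_points": [10], "labels": ["adequate", "high"]},
    {"nutrient": "sodium_mg", "unit": "salt_g", "cut_points": [6], "labels": ["adequate", "high"]},
    {"nutrient": "fiber_g", "unit": "absolute", "cut_points": [25], "labels": ["low", "adequate"]},
    {"nutrient": "calcium_mg", "unit": "absolute", "cut_points": [800, 2500], "labels": ["low", "adequate", "high"]},
    {"nutrient": "iron_mg", "unit": "absolute", "cut_points": [14, 45], "labels": ["low", "adequate", "high"]},
    {"nutrient": "folate_ug", "unit": "absolute", "cut_points": [330, 1000], "labels": ["low", "adequate", "high"]},
    {"nutrient": "thiamin_mg", "unit": "absolute", "cut_points": [1.1], "labels": ["low", "adequate"]},
    {"nutrient": "riboflavin_mg", "unit": "absolute", "cut_points": [1.1], "labels": ["low", "adequate"]},
    {"nutrient": "vitamin_c_mg", "unit": "absolute", "cut_points": [110, 1000], "labels": ["low", "adequate", "high"]}
  ]
}
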