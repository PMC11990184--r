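food_code,source_group,servings_per_100g
10000001,whole_grains,1.2
10000002,fruits,0.8
10000003,vegetables,1.0
10000004,legumes,2.0
10000005,unsaturated_oils,7.0
10000006,refined_grains,1.1
10000007,fruit_juices,0.5
10000008,sugars_syrups,4.0
10000009,dairy_medium_fat,0.25
10000009,dairy_high_fat,0.15
10000010,dairy_high_fat,1.5
10000011,red_meat_regular,1.3
10000012,poultry_lean,1.2
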