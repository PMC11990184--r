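food_code,description,energy_density_kj_100g,is_recipe
10000001,"rolled oats",1500,FALSE
10000002,"apple, raw",220,FALSE
10000003,"broccoli, boiled",140,FALSE
10000004,"lentils, dried",1400,FALSE
10000005,"olive oil",3700,FALSE
10000006,"white bread",1000,FALSE
10000007,"orange juice, from concentrate",180,FALSE
10000008,"white sugar",1700,FALSE
10000009,"milk, regular fat",270,FALSE
10000010,"cheddar cheese",1700,FALSE
10000011,"beef mince, regular",900,FALSE
10000012,"chicken breast, lean",500,FALSE
30000001,"homemade lentil soup",896,TRUE
30000002,"homemade beef stew",1232,TRUE
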