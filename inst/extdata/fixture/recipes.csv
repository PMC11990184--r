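parent_code,ingredient_code,weight_fraction
30000001,10000004,0.6
30000001,10000003,0.4
30000002,10000011,0.5
30000002,10000003,0.3
30000002,10000005,0.2
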