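food_code,nova_group
10000001,1
10000002,1
10000003,1
10000004,1
10000005,2
10000006,4
10000007,4
10000008,2
10000009,1
10000010,3
10000011,1
10000012,1
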