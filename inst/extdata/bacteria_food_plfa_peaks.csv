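sample_id,fatty_acid,area,delta13c_fame
bacteria_food_1,C16:0,23.8000000000,-28.5
bacteria_food_1,C18:1,63.2277777778,-27.9
bacteria_food_1,C18:0,18.6833333333,-28.2
bacteria_food_1,C19:0,5000,-30
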