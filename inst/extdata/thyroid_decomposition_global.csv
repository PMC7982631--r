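sex,n_1990,n_2017,e_growth,e_growth_aging
both,95026,255489,143690,171003
female,70852,179401,107541,126227
male,24174,76088,36416,44676
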