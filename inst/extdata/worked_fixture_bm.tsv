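query	verdict	best_distance
sp1_ind1	correct	0.00840355915819
sp1_ind2	correct	0.00840355915819
sp1_ind3	correct	0.00840355915819
sp2_ind1	correct	0.00840355915819
sp2_ind2	correct	0.00840355915819
sp2_ind3	correct	0.00840355915819
sp3_ind1	correct	0.00840355915819
sp3_ind2	correct	0.00840355915819
sp3_ind3	correct	0.00840355915819
sp4_ind1	correct	0.00840355915819
sp4_ind2	correct	0.00840355915819
sp4_ind3	correct	0.00840355915819
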