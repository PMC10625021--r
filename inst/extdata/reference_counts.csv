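quantity,numerator,denominator,printed_pct
cluster1_share,35975,54545,66
cluster2_share,6543,54545,12
cluster3_share,11375,54545,21
cluster4_share,652,54545,1
ambulatory_subgroup_share,11405,54545,21
prescriber_hospital_share,35387,54545,65
prescriber_private_pulmonologist_share,14069,54545,26
cluster4_undernutrition,432,652,66
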