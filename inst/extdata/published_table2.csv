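scenario,k_per_h,Td_days,GF_pct,dormant_pct,stem_pct,limp_pct,diff_pct,dead_pct
typical,0.001,29,14,18,12,20,62,6
T1,0.0004,72,15,36,32,19,40,9
T2,0.0004,72,19,16,14,21,59,6
T3,0.001,29,14,18,12,20,62,6
T4,0.0014,21,37,14,35,16,2,47
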