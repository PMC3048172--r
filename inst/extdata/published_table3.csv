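scenario,reduction_pct,GF_pct,dormant_pct,stem_pct,limp_pct,diff_pct,dead_pct
typical,56,7,13,7,13,74,6
T1,72,10,27,23,14,55,8
T2,72,11,11,8,14,73,5
T3,72,6,11,7,10,78,5
T4,73,30,12,29,13,1,57
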