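body_region_group,n_curative,pct_curative,n_palliative,pct_palliative
Chest,123378,91,12144,9
Organs and tissues in pelvis region,78220,97,2211,3
Pelvis - single side,1057,44,1332,56
Pelvis - both sides,27902,91,2685,9
Brain,9177,52,8589,48
Neck,16378,92,1336,8
Head,14256,93,1020,7
Bone - spine/limb/chest/head,3817,21,14353,79
Abdomen,7206,73,2614,27
Skin,983,73,357,27
Other regions,7116,96,262,4
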