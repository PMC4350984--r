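site_group,n_curative,pct_curative,n_palliative,pct_palliative
Head/neck,26090,97,924,3
Other head/neck,3735,92,309,8
Colon/intestines,1782,58,1271,42
Rectum,17585,91,1709,9
Liver,140,38,226,62
Other GI,6736,74,2349,26
Lung,18850,55,15319,45
Bone,245,68,114,32
Soft tissue,1942,86,303,14
Melanoma,1390,54,1204,46
Skin,134,85,23,15
Breast,97728,93,6897,7
Ovary,461,46,541,54
Other GYN,12791,90,1391,10
Prostate/Testis/Penis,74061,95,3896,5
Bladder,2206,67,1075,33
Kidney,464,24,1504,76
CNS,7524,93,604,7
Thyroid/Endo,727,70,318,30
Unspecified group 1,1271,88,176,12
Unspecified group 2,4152,66,2153,34
Lymphoid/leukemia,7295,71,2933,29
Hodgkin's disease,1697,94,116,6
Myeloma,484,24,1548,76
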