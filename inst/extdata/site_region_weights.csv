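site_group,body_region_group,w_curative,w_palliative
Breast,Chest,30,4
Prostate/Testis/Penis,Organs and tissues in pelvis region,22,1
Lung,Chest,6,22
Head/neck,Neck,4.5,0.4
Head/neck,Head,3.5,0.2
Rectum,Pelvis - both sides,5,0.5
Rectum,Pelvis - single side,0.3,0.4
Other GYN,Pelvis - both sides,3.5,0.4
CNS,Brain,2.2,0.2
Lymphoid/leukemia,Other regions,2,0.5
Hodgkin's disease,Chest,0.5,0.05
Soft tissue,Other regions,0.6,0.1
Skin,Skin,0.3,0.1
Bladder,Organs and tissues in pelvis region,0.6,0.3
Unspecified group 1,Neck,0.4,0.1
Breast,Bone - spine/limb/chest/head,0.3,14
Prostate/Testis/Penis,Bone - spine/limb/chest/head,0.2,11
Lung,Bone - spine/limb/chest/head,0.2,8
Lung,Brain,0.3,8
Breast,Brain,0.1,4
Melanoma,Brain,0.1,2.5
Myeloma,Bone - spine/limb/chest/head,0.3,4.5
Kidney,Bone - spine/limb/chest/head,0.1,2.5
Unspecified group 2,Bone - spine/limb/chest/head,0.2,5
Unspecified group 2,Pelvis - single side,0.1,1
Bone,Bone - spine/limb/chest/head,0.15,0.3
Colon/intestines,Abdomen,0.8,2.5
Liver,Abdomen,0.05,1
Ovary,Abdomen,0.2,1
Other GI,Abdomen,2,2
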