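verbatim,body_region_group
chest,Chest
chest wall,Chest
thorax,Chest
lung,Chest
mediastinum,Chest
breast,Chest
prostate,Organs and tissues in pelvis region
bladder,Organs and tissues in pelvis region
uterus,Organs and tissues in pelvis region
cervix,Organs and tissues in pelvis region
rectum,Organs and tissues in pelvis region
pelvic organs,Organs and tissues in pelvis region
pelvis left,Pelvis - single side
pelvis right,Pelvis - single side
hemipelvis,Pelvis - single side
pelvis,Pelvis - both sides
whole pelvis,Pelvis - both sides
brain,Brain
whole brain,Brain
cranium,Brain
neck,Neck
cervical nodes,Neck
head,Head
face,Head
sinus,Head
spine,Bone - spine/limb/chest/head
cervical spine,Bone - spine/limb/chest/head
thoracic spine,Bone - spine/limb/chest/head
lumbar spine,Bone - spine/limb/chest/head
rib,Bone - spine/limb/chest/head
sternum,Bone - spine/limb/chest/head
skull,Bone - spine/limb/chest/head
femur,Bone - spine/limb/chest/head
humerus,Bone - spine/limb/chest/head
hip,Bone - spine/limb/chest/head
abdomen,Abdomen
liver,Abdomen
stomach,Abdomen
para-aortic nodes,Abdomen
skin,Skin
skin lesion,Skin
axilla,Other regions
groin,Other regions
extremity,Other regions
limb soft tissue,Other regions
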