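id,source,sign,target,category,source_kind,target_kind,source_compartment,target_compartment
emt01,TGFB,activation,TGFBR,state_transition,protein,complex,extracellular,membrane
emt02,TGFBR,activation,SMAD,state_transition,complex,complex,membrane,nucleus
emt03,SMAD,activation,SNAIL,state_transition,complex,protein,nucleus,nucleus
emt04,NFKB,activation,SNAIL,state_transition,protein,protein,nucleus,nucleus
emt05,GSK3B,inhibition,SNAIL,state_transition,protein,protein,cytoplasm,nucleus
emt06,miR34,inhibition,SNAIL,state_transition,rna,protein,cytoplasm,nucleus
emt07,SNAIL,inhibition,miR34,state_transition,protein,rna,nucleus,cytoplasm
emt08,ZEB,inhibition,miR34,state_transition,protein,rna,nucleus,cytoplasm
emt09,SNAIL,inhibition,miR200,state_transition,protein,rna,nucleus,cytoplasm
emt10,ZEB,inhibition,miR200,state_transition,protein,rna,nucleus,cytoplasm
emt11,miR200,inhibition,ZEB,state_transition,rna,protein,cytoplasm,nucleus
emt12,SNAIL,activation,ZEB,state_transition,protein,protein,nucleus,nucleus
emt13,GRHL2,inhibition,ZEB,state_transition,protein,protein,nucleus,nucleus
emt14,ZEB,inhibition,GRHL2,state_transition,protein,protein,nucleus,nucleus
emt15,OVOL2,inhibition,ZEB,state_transition,protein,protein,nucleus,nucleus
emt16,ZEB,inhibition,OVOL2,state_transition,protein,protein,nucleus,nucleus
emt17,SNAIL,inhibition,GRHL2,state_transition,protein,protein,nucleus,nucleus
emt18,SNAIL,inhibition,OVOL2,state_transition,protein,protein,nucleus,nucleus
emt19,SNAIL,inhibition,ECadherin,state_transition,protein,protein,nucleus,membrane
emt20,SNAIL,inhibition,ZO1,state_transition,protein,protein,nucleus,membrane
emt21,TGFBR,activation,AKT,state_transition,complex,protein,membrane,cytoplasm
emt22,TWIST,activation,AKT,state_transition,protein,protein,nucleus,cytoplasm
emt23,AKT,activation,TWIST,state_transition,protein,protein,cytoplasm,nucleus
emt24,AKT,inhibition,GSK3B,state_transition,protein,protein,cytoplasm,cytoplasm
emt25,AKT,activation,NFKB,state_transition,protein,protein,cytoplasm,nucleus
emt26,NFKB,activation,NKILA,state_transition,protein,rna,nucleus,cytoplasm
emt27,NKILA,inhibition,NFKB,state_transition,rna,protein,cytoplasm,nucleus
emt28,SNAIL,activation,Goosecoid,state_transition,protein,protein,nucleus,nucleus
emt29,SNAIL,activation,NCadherin,state_transition,protein,protein,nucleus,membrane
emt30,ZEB,activation,NCadherin,state_transition,protein,protein,nucleus,membrane
emt31,p53,activation,miR200,state_transition,protein,rna,nucleus,cytoplasm
emt32,p53,activation,miR34,state_transition,protein,rna,nucleus,cytoplasm
emt33,MDM2,inhibition,p53,state_transition,protein,protein,nucleus,nucleus
emt34,SMAD,activation,MDM2,state_transition,complex,protein,nucleus,nucleus
emt35,SNAIL,activation,EMT,logical_activation,protein,phenotype,nucleus,cytoplasm
emt36,ZEB,activation,EMT,logical_activation,protein,phenotype,nucleus,cytoplasm
emt37,TWIST,activation,EMT,logical_activation,protein,phenotype,nucleus,cytoplasm
emt38,ECadherin,inhibition,EMT,logical_activation,protein,phenotype,membrane,cytoplasm
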