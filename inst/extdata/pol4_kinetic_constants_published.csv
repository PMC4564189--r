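enzyme,template,lesion,dntp,kd_um,kd_qualifier,kpol_s,kpol_qualifier,reported_eff,eff_sig_figs
PolIV,13/20G,none,dCTP,300,>,5,~,16700,3
PolIV,13/20MeG,O6-mdG,dCTP,83,,0.0060,,72,2
PolIV,13/20MeG,O6-mdG,dTTP,121,,0.0047,,38,2
PolIV,13/20A,none,dTTP,207,,0.902,,4360,3
PolIV,13/20MeA,3d-medA,dTTP,350,,0.345,,990,2
PolIV,13/20Sp,AP,dATP,NA,,NA,,NA,NA
PolIV-T120P,13/20G,none,dCTP,14.0,,0.58,,41400,3
PolIV-T120P,13/20MeG,O6-mdG,dCTP,60,,0.0098,,163,3
PolIV-T120P,13/20MeG,O6-mdG,dTTP,118.5,,0.014,,120,2
PolIV-T120P,13/20A,none,dTTP,39,,0.481,,2300,2
PolIV-T120P,13/20MeA,3d-medA,dTTP,34,,0.050,,1470,3
PolIV-T120P,13/20Sp,AP,dATP,460,,0.0073,,16,2
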