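material,endpoint,loaec_ug_per_ml,mm2_printed,determined
Quartz DQ12,LDH,90,720,TRUE
Quartz DQ12,GLU,90,720,TRUE
Quartz DQ12,TNF,45,360,TRUE
Quartz DQ12,H2O2,NA,NA,TRUE
TiO2 NM-105,LDH,90,4230,TRUE
TiO2 NM-105,GLU,90,4230,TRUE
TiO2 NM-105,TNF,90,4230,TRUE
TiO2 NM-105,H2O2,NA,NA,TRUE
ZnO NM-111,LDH,5.6,84,TRUE
ZnO NM-111,GLU,90,1350,TRUE
ZnO NM-111,TNF,22.5,338,TRUE
ZnO NM-111,H2O2,NA,NA,TRUE
nano-CeO2,LDH,90,2970,TRUE
nano-CeO2,GLU,180,NA,TRUE
nano-CeO2,TNF,45,1485,TRUE
nano-CeO2,H2O2,NA,NA,TRUE
Al-doped CeO2,LDH,45,2070,TRUE
Al-doped CeO2,GLU,90,4140,TRUE
Al-doped CeO2,TNF,22.5,1035,TRUE
Al-doped CeO2,H2O2,NA,NA,TRUE
CeO2 NM-211,LDH,90,5940,TRUE
CeO2 NM-211,GLU,180,NA,TRUE
CeO2 NM-211,TNF,22.5,1485,TRUE
CeO2 NM-211,H2O2,NA,NA,TRUE
CeO2 NM-212,LDH,90,2430,TRUE
CeO2 NM-212,GLU,180,NA,TRUE
CeO2 NM-212,TNF,22.5,608,TRUE
CeO2 NM-212,H2O2,NA,NA,TRUE
SiO2.naked,LDH,22.5,4500,TRUE
SiO2.naked,GLU,45,9000,TRUE
SiO2.naked,TNF,22.5,4500,TRUE
SiO2.naked,H2O2,45,9000,TRUE
SiO2.PEG,LDH,90,18000,TRUE
SiO2.PEG,GLU,90,18000,TRUE
SiO2.PEG,TNF,90,18000,TRUE
SiO2.PEG,H2O2,180,36000,TRUE
SiO2.amino,LDH,45,9000,TRUE
SiO2.amino,GLU,45,9000,TRUE
SiO2.amino,TNF,22.5,4500,TRUE
SiO2.amino,H2O2,180,36000,TRUE
SiO2.phosphate,LDH,90,18000,TRUE
SiO2.phosphate,GLU,180,NA,TRUE
SiO2.phosphate,TNF,90,18000,TRUE
SiO2.phosphate,H2O2,45,9000,TRUE
SiO2 NM-200,LDH,22.5,4253,TRUE
SiO2 NM-200,GLU,22.5,4253,TRUE
SiO2 NM-200,TNF,22.5,4253,TRUE
SiO2 NM-200,H2O2,NA,NA,TRUE
SiO2 NM-203,LDH,22.5,4500,TRUE
SiO2 NM-203,GLU,22.5,4500,TRUE
SiO2 NM-203,TNF,22.5,4500,TRUE
SiO2 NM-203,H2O2,NA,NA,TRUE
AlOOH,LDH,90,9450,TRUE
AlOOH,GLU,NA,NA,TRUE
AlOOH,TNF,180,18900,TRUE
AlOOH,H2O2,NA,NA,TRUE
BaSO4 NM-220,LDH,NA,NA,TRUE
BaSO4 NM-220,GLU,NA,NA,TRUE
BaSO4 NM-220,TNF,NA,NA,TRUE
BaSO4 NM-220,H2O2,NA,NA,TRUE
Fe2O3 (hematite),LDH,NA,NA,TRUE
Fe2O3 (hematite),GLU,NA,NA,TRUE
Fe2O3 (hematite),TNF,90,8266,TRUE
Fe2O3 (hematite),H2O2,NA,NA,TRUE
ZrO2.TODA,LDH,45,5265,TRUE
ZrO2.TODA,GLU,NA,NA,TRUE
ZrO2.TODA,TNF,90,10530,TRUE
ZrO2.TODA,H2O2,90,10530,TRUE
ZrO2.acrylate,LDH,70.5,8249,TRUE
ZrO2.acrylate,GLU,141,16497,TRUE
ZrO2.acrylate,TNF,70.5,8249,TRUE
ZrO2.acrylate,H2O2,141,16497,TRUE
DPP Orange N,LDH,NA,NA,TRUE
DPP Orange N,GLU,NA,NA,TRUE
DPP Orange N,TNF,45,2880,TRUE
DPP Orange N,H2O2,NA,NA,TRUE
Pigment Blue 15:1,LDH,90,4770,TRUE
Pigment Blue 15:1,GLU,90,4770,TRUE
Pigment Blue 15:1,TNF,NA,NA,FALSE
Pigment Blue 15:1,H2O2,NA,NA,TRUE
Graphite nanoplatelets,LDH,NA,NA,TRUE
Graphite nanoplatelets,GLU,45,3330,TRUE
Graphite nanoplatelets,TNF,90,6660,TRUE
Graphite nanoplatelets,H2O2,NA,NA,TRUE
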