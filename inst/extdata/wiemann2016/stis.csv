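material,noaec_mg_m3,noaec_bound,loaec_mg_m3,exposure_days,role,reference
Quartz DQ12,0.1,exact,1.0,5,positive_control,CR106
TiO2 NM-105,2,below,2.0,5,test,CR10
ZnO NM-111,0.5,exact,2.5,5,test,CR11
nano-CeO2,0.5,exact,2.5,5,test,CR11
Al-doped CeO2,0.5,exact,2.0,5,test,CR11
CeO2 NM-211,0.5,below,5.0,5,test,CR111
CeO2 NM-212,0.5,below,5.0,5,test,CR111
SiO2.naked,2.5,exact,10,5,test,CR11
SiO2.PEG,50,at_least,NA,5,test,CR11
SiO2.amino,50,at_least,NA,5,test,CR11
SiO2.phosphate,50,at_least,NA,5,test,CR11
SiO2 NM-200,1,exact,5,5,test,CR80
SiO2 NM-203,1,exact,5,5,test,CR80
AlOOH,3,exact,28,28,test,CR58
BaSO4 NM-220,50,at_least,NA,5,test,CR11
Fe2O3 (hematite),30,at_least,NA,5,test,CR79
ZrO2.TODA,50,at_least,NA,5,test,CR11
ZrO2.acrylate,50,at_least,NA,5,test,CR11
DPP Orange N,30,at_least,NA,5,test,CR79
Pigment Blue 15:1,30,at_least,NA,5,test,CR79
Graphite nanoplatelets,10,at_least,NA,5,test,CR82
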