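name,material_class,bet_m2_per_g,form,primary_particle_size_nm,series_ldh,series_glu,series_tnf,series_h2o2,notes
Corundum,benchmark control (negative),NA,powder,micron-sized,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,micron-scale negative benchmark; no BET reported; excluded from surface-area conversion
Quartz DQ12,micron-sized crystalline silica (positive control),8,powder,micron-sized,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,BET from STIS comparison table
TiO2 NM-105,metal oxide NM,47,powder,28,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
ZnO NM-111,metal oxide NM,15,powder,82,0;2.8;5.6;11.3;22.5,0;22.5;45;90;180,0;2.8;5.6;11.3;22.5,0;22.5;45;90;180,high bioactivity; LDH/TNF tested at 2.8-22.5 ug/mL; methods text prints 11.2 where the summary table prints 11.3
nano-CeO2,metal oxide NM,33,powder,40,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
Al-doped CeO2,metal oxide NM,46,powder,2-160,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
CeO2 NM-211,metal oxide NM,66,powder,10-20,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
CeO2 NM-212,metal oxide NM,27,powder,10-20,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2.naked,amorphous SiO2 NM,200,suspension,5-50,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2.PEG,amorphous SiO2 NM,200,suspension,8-45,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2.amino,amorphous SiO2 NM,200,suspension,5-50,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2.phosphate,amorphous SiO2 NM,200,suspension,5-50,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2 NM-200,amorphous SiO2 NM,189,powder,10-20,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
SiO2 NM-203,amorphous SiO2 NM,200,powder,5-30,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
AlOOH,metal oxide NM,105,powder,40,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,BET from STIS comparison table and discussion
BaSO4 NM-220,metal sulphate NM,41,powder,25,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
Fe2O3 (hematite),metal oxide NM,98,powder,15,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
ZrO2.TODA,metal oxide NM,117,suspension,3-15,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
ZrO2.acrylate,metal oxide NM,117,suspension,9,0;35;70.5;141;283,0;35;70.5;141;283,0;35;70.5;141;283,0;35;70.5;141;283,assessed at 35-283 ug/mL for technical reasons
DPP Orange N,nanosized organic pigment,64,powder,30-400 x 10-50,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
Pigment Blue 15:1,nanosized organic pigment,53,powder,17,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,TNF-alpha not determined for technical reasons
Graphite nanoplatelets,carbonaceous NM,74,powder,<30 um flakes,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,0;22.5;45;90;180,
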