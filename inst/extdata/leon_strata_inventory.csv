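stratum_code,dominant_species,area_ha_province,area_ha_jurisd10,nfi_plots_province,nfi_plots_jurisd10
102,Pinus sylvestris,64012.82,8794.10,167,40
103,Pinus pinaster,23413.33,7998.96,58,20
106,Quercus pyrenaica,212017.32,32680.84,322,66
118,Pinus nigra,28631.40,7840.99,95,26
119,Fagus sylvatica,21894.53,9229.60,87,42
121,Quercus spp,15010.45,4629.24,47,14
combined,FT Combined,364979.85,71173.73,725,208
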