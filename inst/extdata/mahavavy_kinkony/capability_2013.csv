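"selu_id","code","value"
"Human footprint","C10",139219
"Agricultural landscape","C10",611150
"Shrubland","C10",1792252
"Forest landscape","C10",505248
"Mangrove Landscape","C10",470378
"Wetland","C10",434790
"Estuary","C10",197525
"Human footprint","CIUV",1
"Agricultural landscape","CIUV",1
"Shrubland","CIUV",1
"Forest landscape","CIUV",0.92
"Mangrove Landscape","CIUV",0.77
"Wetland","CIUV",1
"Estuary","CIUV",1
"Human footprint","W6",24456
"Agricultural landscape","W6",85126
"Shrubland","W6",266749
"Forest landscape","W6",203241
"Mangrove Landscape","W6",53983
"Wetland","W6",85831
"Estuary","W6",18782
"Human footprint","W15",0.72
"Agricultural landscape","W15",0.74
"Shrubland","W15",0.98
"Forest landscape","W15",0.98
"Mangrove Landscape","W15",0.87
"Wetland","W15",0.7
"Estuary","W15",0.97
"Human footprint","TEIP_adj",14348
"Agricultural landscape","TEIP_adj",47757
"Shrubland","TEIP_adj",255524
"Forest landscape","TEIP_adj",242975
"Mangrove Landscape","TEIP_adj",103087
"Wetland","TEIP_adj",325306
"Estuary","TEIP_adj",54324
"Human footprint","EIIUV",0.71
"Agricultural landscape","EIIUV",0.97
"Shrubland","EIIUV",0.93
"Forest landscape","EIIUV",0.81
"Mangrove Landscape","EIIUV",0.9
"Wetland","EIIUV",0.83
"Estuary","EIIUV",0.93
"Human footprint","C_EC",113027
"Agricultural landscape","C_EC",552392
"Shrubland","C_EC",1736426
"Forest landscape","C_EC",455338
"Mangrove Landscape","C_EC",396642
"Wetland","C_EC",365739
"Estuary","C_EC",190670
"Human footprint","W_EC",19855
"Agricultural landscape","W_EC",76942
"Shrubland","W_EC",258441
"Forest landscape","W_EC",183164
"Mangrove Landscape","W_EC",45521
"Wetland","W_EC",72200
"Estuary","W_EC",18130
"Human footprint","EI_EC",11649
"Agricultural landscape","EI_EC",42981
"Shrubland","EI_EC",247566
"Forest landscape","EI_EC",218973
"Mangrove Landscape","EI_EC",86928
"Wetland","EI_EC",273643
"Estuary","EI_EC",52439
"Human footprint","TEC",144532
"Agricultural landscape","TEC",672315
"Shrubland","TEC",2242432
"Forest landscape","TEC",857476
"Mangrove Landscape","TEC",529091
"Wetland","TEC",711581
"Estuary","TEC",261240
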