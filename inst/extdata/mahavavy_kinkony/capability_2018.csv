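"selu_id","code","value"
"Human footprint","C10",144252
"Agricultural landscape","C10",1028158
"Shrubland","C10",1495989
"Forest landscape","C10",481878
"Mangrove Landscape","C10",440956
"Wetland","C10",466831
"Estuary","C10",187854
"Human footprint","CIUV",1
"Agricultural landscape","CIUV",1
"Shrubland","CIUV",0.88
"Forest landscape","CIUV",0.78
"Mangrove Landscape","CIUV",0.74
"Wetland","CIUV",1
"Estuary","CIUV",1
"Human footprint","W6",19621
"Agricultural landscape","W6",111121
"Shrubland","W6",237271
"Forest landscape","W6",185951
"Mangrove Landscape","W6",61976
"Wetland","W6",74761
"Estuary","W6",15869
"Human footprint","W15",0.64
"Agricultural landscape","W15",0.78
"Shrubland","W15",0.98
"Forest landscape","W15",0.98
"Mangrove Landscape","W15",0.81
"Wetland","W15",0.65
"Estuary","W15",0.96
"Human footprint","TEIP_adj",7000
"Agricultural landscape","TEIP_adj",49573
"Shrubland","TEIP_adj",240827
"Forest landscape","TEIP_adj",171053
"Mangrove Landscape","TEIP_adj",86126
"Wetland","TEIP_adj",236614
"Estuary","TEIP_adj",49862
"Human footprint","EIIUV",0.71
"Agricultural landscape","EIIUV",0.97
"Shrubland","EIIUV",0.93
"Forest landscape","EIIUV",0.81
"Mangrove Landscape","EIIUV",0.9
"Wetland","EIIUV",0.83
"Estuary","EIIUV",0.93
"Human footprint","C_EC",111871
"Agricultural landscape","C_EC",931272
"Shrubland","C_EC",1396558
"Forest landscape","C_EC",418890
"Mangrove Landscape","C_EC",359365
"Wetland","C_EC",382281
"Estuary","C_EC",181138
"Human footprint","W_EC",15217
"Agricultural landscape","W_EC",100651
"Shrubland","W_EC",221501
"Forest landscape","W_EC",161645
"Mangrove Landscape","W_EC",50508
"Wetland","W_EC",61221
"Estuary","W_EC",15302
"Human footprint","EI_EC",5429
"Agricultural landscape","EI_EC",45111
"Shrubland","EI_EC",224821
"Forest landscape","EI_EC",148694
"Mangrove Landscape","EI_EC",70190
"Wetland","EI_EC",193760
"Estuary","EI_EC",48079
"Human footprint","TEC",132516
"Agricultural landscape","TEC",1077034
"Shrubland","TEC",1842880
"Forest landscape","TEC",729229
"Mangrove Landscape","TEC",480063
"Wetland","TEC",637262
"Estuary","TEC",244520
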