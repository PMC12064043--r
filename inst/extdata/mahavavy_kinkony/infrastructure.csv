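"selu_id","code","value"
"Human footprint","RC1",6241
"Agricultural landscape","RC1",17408
"Shrubland","RC1",121514
"Forest landscape","RC1",79706
"Mangrove Landscape","RC1",39927
"Wetland","RC1",110957
"Estuary","RC1",21397
"Human footprint","GBLI13",59.91
"Agricultural landscape","GBLI13",59.36
"Shrubland","GBLI13",69.53
"Forest landscape","GBLI13",88.01
"Mangrove Landscape","GBLI13",81.75
"Wetland","GBLI13",79.1
"Estuary","GBLI13",86.23
"Human footprint","HNVI13",1
"Agricultural landscape","HNVI13",1
"Shrubland","HNVI13",1
"Forest landscape","HNVI13",1.14
"Mangrove Landscape","HNVI13",1
"Wetland","HNVI13",1.05
"Estuary","HNVI13",1
"Human footprint","FI13",0.62
"Agricultural landscape","FI13",0.55
"Shrubland","FI13",0.97
"Forest landscape","FI13",0.98
"Mangrove Landscape","FI13",0.98
"Wetland","FI13",0.96
"Estuary","FI13",1
"Human footprint","NLEP13",5216
"Agricultural landscape","NLEP13",12788
"Shrubland","NLEP13",184136
"Forest landscape","NLEP13",176876
"Mangrove Landscape","NLEP13",71846
"Wetland","NLEP13",200129
"Estuary","NLEP13",41486
"Human footprint","RAWI13",53.38
"Agricultural landscape","RAWI13",75.38
"Shrubland","RAWI13",15.43
"Forest landscape","RAWI13",18.77
"Mangrove Landscape","RAWI13",21.69
"Wetland","RAWI13",33.46
"Estuary","RAWI13",13.8
"Human footprint","HNVI_riv13",1
"Agricultural landscape","HNVI_riv13",1
"Shrubland","HNVI_riv13",1
"Forest landscape","HNVI_riv13",1.14
"Mangrove Landscape","HNVI_riv13",1
"Wetland","HNVI_riv13",1.05
"Estuary","HNVI_riv13",1
"Human footprint","frag_riv13",1
"Agricultural landscape","frag_riv13",1
"Shrubland","frag_riv13",1
"Forest landscape","frag_riv13",1
"Mangrove Landscape","frag_riv13",1
"Wetland","frag_riv13",1
"Estuary","frag_riv13",1
"Human footprint","NREP13",7496
"Agricultural landscape","NREP13",29524
"Shrubland","NREP13",42256
"Forest landscape","NREP13",38396
"Mangrove Landscape","NREP13",19489
"Wetland","NREP13",88088
"Estuary","NREP13",6644
"Human footprint","TEIP1",12713
"Agricultural landscape","TEIP1",42312
"Shrubland","TEIP1",226391
"Forest landscape","TEIP1",215273
"Mangrove Landscape","TEIP1",91334
"Wetland","TEIP1",288217
"Estuary","TEIP1",48130
"Human footprint","RC2",6241
"Agricultural landscape","RC2",29596
"Shrubland","RC2",129468
"Forest landscape","RC2",60649
"Mangrove Landscape","RC2",38842
"Wetland","RC2",110957
"Estuary","RC2",21397
"Human footprint","GBLI18",59.37
"Agricultural landscape","GBLI18",65.68
"Shrubland","GBLI18",68.83
"Forest landscape","GBLI18",88.17
"Mangrove Landscape","GBLI18",80.35
"Wetland","GBLI18",76.62
"Estuary","GBLI18",86.52
"Human footprint","HNVI18",1
"Agricultural landscape","HNVI18",1
"Shrubland","HNVI18",1
"Forest landscape","HNVI18",1.19
"Mangrove Landscape","HNVI18",1
"Wetland","HNVI18",1.05
"Estuary","HNVI18",1
"Human footprint","FI18",0.52
"Agricultural landscape","FI18",0.47
"Shrubland","FI18",0.97
"Forest landscape","FI18",0.97
"Mangrove Landscape","FI18",0.97
"Wetland","FI18",0.87
"Estuary","FI18",1
"Human footprint","NLEP18",4341
"Agricultural landscape","NLEP18",20556
"Shrubland","NLEP18",194324
"Forest landscape","NLEP18",139212
"Mangrove Landscape","NLEP18",67824
"Wetland","NLEP18",174479
"Estuary","NLEP18",41613
"Human footprint","RAWI18",15.01
"Agricultural landscape","RAWI18",37.71
"Shrubland","RAWI18",9.44
"Forest landscape","RAWI18",11.32
"Mangrove Landscape","RAWI18",13.18
"Wetland","RAWI18",16.53
"Estuary","RAWI18",8.98
"Human footprint","HNVI_riv18",1
"Agricultural landscape","HNVI_riv18",1
"Shrubland","HNVI_riv18",1
"Forest landscape","HNVI_riv18",1.19
"Mangrove Landscape","HNVI_riv18",1
"Wetland","HNVI_riv18",1.05
"Estuary","HNVI_riv18",1
"Human footprint","frag_riv18",1
"Agricultural landscape","frag_riv18",1
"Shrubland","frag_riv18",1
"Forest landscape","frag_riv18",1
"Mangrove Landscape","frag_riv18",1
"Wetland","frag_riv18",1
"Estuary","frag_riv18",1
"Human footprint","NREP18",2108
"Agricultural landscape","NREP18",25115
"Shrubland","NREP18",27547
"Forest landscape","NREP18",18377
"Mangrove Landscape","NREP18",11523
"Wetland","NREP18",43510
"Estuary","NREP18",4324
"Human footprint","TEIP2",6449
"Agricultural landscape","TEIP2",45671
"Shrubland","TEIP2",221871
"Forest landscape","TEIP2",157589
"Mangrove Landscape","TEIP2",79347
"Wetland","TEIP2",217990
"Estuary","TEIP2",45937
"Human footprint","TEIP1_adj",14349
"Agricultural landscape","TEIP1_adj",47757
"Shrubland","TEIP1_adj",255525
"Forest landscape","TEIP1_adj",242975
"Mangrove Landscape","TEIP1_adj",103088
"Wetland","TEIP1_adj",325306
"Estuary","TEIP1_adj",54324
"Human footprint","TEIP2_adj",7000
"Agricultural landscape","TEIP2_adj",49573
"Shrubland","TEIP2_adj",240828
"Forest landscape","TEIP2_adj",171053
"Mangrove Landscape","TEIP2_adj",86127
"Wetland","TEIP2_adj",236615
"Estuary","TEIP2_adj",49862
"Human footprint","EHI",0.94
"Agricultural landscape","EHI",0.94
"Shrubland","EHI",0.92
"Forest landscape","EHI",0.92
"Mangrove Landscape","EHI",0.96
"Wetland","EHI",0.93
"Estuary","EHI",0.94
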