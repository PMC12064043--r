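"selu_id","code","value"
"Human footprint","W1_1",21902
"Agricultural landscape","W1_1",631953
"Shrubland","W1_1",65950
"Forest landscape","W1_1",53272
"Mangrove Landscape","W1_1",245213
"Wetland","W1_1",1881588
"Estuary","W1_1",232905
"Human footprint","W1_2",1560
"Agricultural landscape","W1_2",91233
"Shrubland","W1_2",19085
"Forest landscape","W1_2",52114
"Mangrove Landscape","W1_2",34641
"Wetland","W1_2",33945
"Estuary","W1_2",101
"Human footprint","W1_4",11924
"Agricultural landscape","W1_4",52085
"Shrubland","W1_4",447648
"Forest landscape","W1_4",125536
"Mangrove Landscape","W1_4",384629
"Wetland","W1_4",40479
"Estuary","W1_4",21999
"Human footprint","W1_5",4169
"Agricultural landscape","W1_5",16436
"Shrubland","W1_5",10240
"Forest landscape","W1_5",44797
"Mangrove Landscape","W1_5",63078
"Wetland","W1_5",11399
"Estuary","W1_5",3910
"Human footprint","W2_1",13556
"Agricultural landscape","W2_1",60836
"Shrubland","W2_1",123516
"Forest landscape","W2_1",148094
"Mangrove Landscape","W2_1",106165
"Wetland","W2_1",44977
"Estuary","W2_1",23556
"Human footprint","W2_2",-52918
"Agricultural landscape","W2_2",-190448
"Shrubland","W2_2",-1177985
"Forest landscape","W2_2",-213204
"Mangrove Landscape","W2_2",-2155697
"Wetland","W2_2",-114477
"Estuary","W2_2",-274299
"Human footprint","W2_3",54880
"Agricultural landscape","W2_3",267173
"Shrubland","W2_3",1264727
"Forest landscape","W2_3",297375
"Mangrove Landscape","W2_3",2983773
"Wetland","W2_3",187558
"Estuary","W2_3",381044
"Human footprint","W2_4",3359
"Agricultural landscape","W2_4",10077
"Shrubland","W2_4",54257
"Forest landscape","W2_4",17204
"Mangrove Landscape","W2_4",1944
"Wetland","W2_4",11645
"Estuary","W2_4",41
"Human footprint","W2_5",5
"Agricultural landscape","W2_5",23
"Shrubland","W2_5",26
"Forest landscape","W2_5",18
"Mangrove Landscape","W2_5",7
"Wetland","W2_5",4
"Estuary","W2_5",0
"Human footprint","W2_6",7832
"Agricultural landscape","W2_6",23487
"Shrubland","W2_6",126536
"Forest landscape","W2_6",40122
"Mangrove Landscape","W2_6",4463
"Wetland","W2_6",27167
"Estuary","W2_6",93
"Human footprint","W3_1",13261
"Agricultural landscape","W3_1",51540
"Shrubland","W3_1",85930
"Forest landscape","W3_1",145897
"Mangrove Landscape","W3_1",47569
"Wetland","W3_1",47015
"Estuary","W3_1",18649
"Human footprint","W3_3",2256
"Agricultural landscape","W3_3",86021
"Shrubland","W3_3",124327
"Forest landscape","W3_3",86368
"Mangrove Landscape","W3_3",886672
"Wetland","W3_3",71044
"Estuary","W3_3",111653
"Human footprint","W3_4",35872
"Agricultural landscape","W3_4",107710
"Shrubland","W3_4",57930
"Forest landscape","W3_4",18371
"Mangrove Landscape","W3_4",21405
"Wetland","W3_4",124263
"Estuary","W3_4",464
"Human footprint","W3_8",0
"Agricultural landscape","W3_8",38
"Shrubland","W3_8",1181
"Forest landscape","W3_8",78
"Mangrove Landscape","W3_8",2223
"Wetland","W3_8",27
"Estuary","W3_8",98
"Human footprint","W14",0.95
"Agricultural landscape","W14",0.95
"Shrubland","W14",0.95
"Forest landscape","W14",0.95
"Mangrove Landscape","W14",0.95
"Wetland","W14",0.89
"Estuary","W14",0.95
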