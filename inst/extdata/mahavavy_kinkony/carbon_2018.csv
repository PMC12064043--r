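"selu_id","code","value"
"Human footprint","C1_1",218319
"Agricultural landscape","C1_1",1639711
"Shrubland","C1_1",1035681
"Forest landscape","C1_1",7189968
"Mangrove Landscape","C1_1",6679512
"Wetland","C1_1",668015
"Estuary","C1_1",317357
"Human footprint","C1_2",26198
"Agricultural landscape","C1_2",196765
"Shrubland","C1_2",124282
"Forest landscape","C1_2",939335
"Mangrove Landscape","C1_2",801541
"Wetland","C1_2",80162
"Estuary","C1_2",38083
"Human footprint","C1_31",132078
"Agricultural landscape","C1_31",876054
"Shrubland","C1_31",562797
"Forest landscape","C1_31",3710963
"Mangrove Landscape","C1_31",3323126
"Wetland","C1_31",353744
"Estuary","C1_31",167367
"Human footprint","C1_32",6268
"Agricultural landscape","C1_32",48613
"Shrubland","C1_32",253675
"Forest landscape","C1_32",53078
"Mangrove Landscape","C1_32",232497
"Wetland","C1_32",20902
"Estuary","C1_32",12449
"Human footprint","C1_4",95
"Agricultural landscape","C1_4",731
"Shrubland","C1_4",3086
"Forest landscape","C1_4",665
"Mangrove Landscape","C1_4",1921
"Wetland","C1_4",397
"Estuary","C1_4",147
"Human footprint","C2_3",191660
"Agricultural landscape","C2_3",1335774
"Shrubland","C2_3",930326
"Forest landscape","C2_3",5376135
"Mangrove Landscape","C2_3",4423786
"Wetland","C2_3",595022
"Estuary","C2_3",252775
"Human footprint","C2",393299
"Agricultural landscape","C2",2779237
"Shrubland","C2",2282224
"Forest landscape","C2",10525031
"Mangrove Landscape","C2",8931563
"Wetland","C2",1236664
"Estuary","C2",519903
"Human footprint","C3_11",1046
"Agricultural landscape","C3_11",1991
"Shrubland","C3_11",1727
"Forest landscape","C3_11",135
"Mangrove Landscape","C3_11",56
"Wetland","C3_11",3224
"Estuary","C3_11",11
"Human footprint","C3_13",1596
"Agricultural landscape","C3_13",24062
"Shrubland","C3_13",0
"Forest landscape","C3_13",0
"Mangrove Landscape","C3_13",0
"Wetland","C3_13",0
"Estuary","C3_13",0
"Human footprint","C3_199",61
"Agricultural landscape","C3_199",321
"Shrubland","C3_199",21
"Forest landscape","C3_199",16
"Mangrove Landscape","C3_199",4
"Wetland","C3_199",288
"Estuary","C3_199",0
"Human footprint","C3_3",17371
"Agricultural landscape","C3_3",101076
"Shrubland","C3_3",542225
"Forest landscape","C3_3",161617
"Mangrove Landscape","C3_3",292962
"Wetland","C3_3",45690
"Estuary","C3_3",20263
"Human footprint","C3_4",61137
"Agricultural landscape","C3_4",395911
"Shrubland","C3_4",954505
"Forest landscape","C3_4",409015
"Mangrove Landscape","C3_4",449492
"Wetland","C3_4",171400
"Estuary","C3_4",27660
"Human footprint","C3",121539
"Agricultural landscape","C3",793848
"Shrubland","C3",1853105
"Forest landscape","C3",809645
"Mangrove Landscape","C3",847758
"Wetland","C3",338729
"Estuary","C3",52974
"Human footprint","C4_33",3588
"Agricultural landscape","C4_33",19248
"Shrubland","C4_33",47493
"Forest landscape","C4_33",11974
"Mangrove Landscape","C4_33",46142
"Wetland","C4_33",3457
"Estuary","C4_33",2327
"Human footprint","C4_34",4840
"Agricultural landscape","C4_34",32582
"Shrubland","C4_34",42481
"Forest landscape","C4_34",28545
"Mangrove Landscape","C4_34",12625
"Wetland","C4_34",14047
"Estuary","C4_34",605
"Human footprint","C10_1",206075
"Agricultural landscape","C10_1",1445065
"Shrubland","C10_1",1900312
"Forest landscape","C10_1",4818784
"Mangrove Landscape","C10_1",4409565
"Wetland","C10_1",645816
"Estuary","C10_1",268364
"Human footprint","C10_2",0.7
"Agricultural landscape","C10_2",0.72
"Shrubland","C10_2",0.8
"Forest landscape","C10_2",0.1
"Mangrove Landscape","C10_2",0.1
"Wetland","C10_2",0.73
"Estuary","C10_2",0.7
"Human footprint","CEH",1
"Agricultural landscape","CEH",1
"Shrubland","CEH",1
"Forest landscape","CEH",1
"Mangrove Landscape","CEH",1
"Wetland","CEH",1
"Estuary","CEH",1
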