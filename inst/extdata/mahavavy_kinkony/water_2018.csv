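"selu_id","code","value"
"Human footprint","W1_1",8690
"Agricultural landscape","W1_1",460471
"Shrubland","W1_1",27159
"Forest landscape","W1_1",19364
"Mangrove Landscape","W1_1",210324
"Wetland","W1_1",1746585
"Estuary","W1_1",46205
"Human footprint","W1_2",1547
"Agricultural landscape","W1_2",131401
"Shrubland","W1_2",21510
"Forest landscape","W1_2",11479
"Mangrove Landscape","W1_2",31093
"Wetland","W1_2",33671
"Estuary","W1_2",100
"Human footprint","W1_4",11454
"Agricultural landscape","W1_4",77640
"Shrubland","W1_4",465890
"Forest landscape","W1_4",93036
"Mangrove Landscape","W1_4",333535
"Wetland","W1_4",38884
"Estuary","W1_4",21132
"Human footprint","W1_5",2363
"Agricultural landscape","W1_5",14224
"Shrubland","W1_5",63305
"Forest landscape","W1_5",20996
"Mangrove Landscape","W1_5",31830
"Wetland","W1_5",6618
"Estuary","W1_5",2235
"Human footprint","W2_1",7149
"Agricultural landscape","W2_1",49191
"Shrubland","W2_1",119260
"Forest landscape","W2_1",146731
"Mangrove Landscape","W2_1",103916
"Wetland","W2_1",43151
"Estuary","W2_1",21629
"Human footprint","W2_2",-41746
"Agricultural landscape","W2_2",-243909
"Shrubland","W2_2",-2477019
"Forest landscape","W2_2",-68268
"Mangrove Landscape","W2_2",-1052898
"Wetland","W2_2",-88201
"Estuary","W2_2",-210773
"Human footprint","W2_3",43550
"Agricultural landscape","W2_3",320972
"Shrubland","W2_3",2569369
"Forest landscape","W2_3",151721
"Mangrove Landscape","W2_3",1780934
"Wetland","W2_3",148836
"Estuary","W2_3",302376
"Human footprint","W2_4",3910
"Agricultural landscape","W2_4",20746
"Shrubland","W2_4",44245
"Forest landscape","W2_4",12305
"Mangrove Landscape","W2_4",2965
"Wetland","W2_4",9902
"Estuary","W2_4",38
"Human footprint","W2_5",4
"Agricultural landscape","W2_5",21
"Shrubland","W2_5",24
"Forest landscape","W2_5",14
"Mangrove Landscape","W2_5",4
"Wetland","W2_5",3
"Estuary","W2_5",0
"Human footprint","W2_6",9118
"Agricultural landscape","W2_6",48376
"Shrubland","W2_6",103158
"Forest landscape","W2_6",28691
"Mangrove Landscape","W2_6",6842
"Wetland","W2_6",23099
"Estuary","W2_6",84
"Human footprint","W3_1",6589
"Agricultural landscape","W3_1",41979
"Shrubland","W3_1",89845
"Forest landscape","W3_1",144942
"Mangrove Landscape","W3_1",52164
"Wetland","W3_1",41758
"Estuary","W3_1",15748
"Human footprint","W3_3",2364
"Agricultural landscape","W3_3",84275
"Shrubland","W3_3",121765
"Forest landscape","W3_3",85241
"Mangrove Landscape","W3_3",779787
"Wetland","W3_3",62028
"Estuary","W3_3",97484
"Human footprint","W3_4",52132
"Agricultural landscape","W3_4",138291
"Shrubland","W3_4",58984
"Forest landscape","W3_4",16404
"Mangrove Landscape","W3_4",39454
"Wetland","W3_4",132018
"Estuary","W3_4",498
"Human footprint","W3_8",0
"Agricultural landscape","W3_8",65
"Shrubland","W3_8",1409
"Forest landscape","W3_8",3
"Mangrove Landscape","W3_8",2191
"Wetland","W3_8",28
"Estuary","W3_8",120
"Human footprint","W14",0.95
"Agricultural landscape","W14",0.95
"Shrubland","W14",0.95
"Forest landscape","W14",0.95
"Mangrove Landscape","W14",0.95
"Wetland","W14",0.87
"Estuary","W14",0.95
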