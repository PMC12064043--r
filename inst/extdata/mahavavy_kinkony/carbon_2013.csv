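"selu_id","code","value"
"Human footprint","C1_1",223553
"Agricultural landscape","C1_1",1057753
"Shrubland","C1_1",1708762
"Forest landscape","C1_1",8247555
"Mangrove Landscape","C1_1",7739968
"Wetland","C1_1",712260
"Estuary","C1_1",327633
"Human footprint","C1_2",26826
"Agricultural landscape","C1_2",126930
"Shrubland","C1_2",205051
"Forest landscape","C1_2",989707
"Mangrove Landscape","C1_2",928796
"Wetland","C1_2",85471
"Estuary","C1_2",39316
"Human footprint","C1_31",133014
"Agricultural landscape","C1_31",582026
"Shrubland","C1_31",944209
"Forest landscape","C1_31",3937828
"Mangrove Landscape","C1_31",4015635
"Wetland","C1_31",379369
"Estuary","C1_31",177264
"Human footprint","C1_32",6134
"Agricultural landscape","C1_32",32721
"Shrubland","C1_32",223141
"Forest landscape","C1_32",68518
"Mangrove Landscape","C1_32",251363
"Wetland","C1_32",20425
"Estuary","C1_32",12243
"Human footprint","C1_4",94
"Agricultural landscape","C1_4",418
"Shrubland","C1_4",2909
"Forest landscape","C1_4",944
"Mangrove Landscape","C1_4",2203
"Wetland","C1_4",388
"Estuary","C1_4",151
"Human footprint","C2_3",207658
"Agricultural landscape","C2_3",891086
"Shrubland","C2_3",1493705
"Forest landscape","C2_3",5715808
"Mangrove Landscape","C2_3",4593957
"Wetland","C2_3",607149
"Estuary","C2_3",262628
"Human footprint","C2",402358
"Agricultural landscape","C2",1764273
"Shrubland","C2",3288089
"Forest landscape","C2",11087464
"Mangrove Landscape","C2",9457152
"Wetland","C2",1205660
"Estuary","C2",546297
"Human footprint","C3_11",913
"Agricultural landscape","C3_11",1676
"Shrubland","C3_11",325
"Forest landscape","C3_11",171
"Mangrove Landscape","C3_11",52
"Wetland","C3_11",1615
"Estuary","C3_11",7
"Human footprint","C3_13",1362
"Agricultural landscape","C3_13",18643
"Shrubland","C3_13",0
"Forest landscape","C3_13",0
"Mangrove Landscape","C3_13",0
"Wetland","C3_13",0
"Estuary","C3_13",0
"Human footprint","C3_199",32
"Agricultural landscape","C3_199",132
"Shrubland","C3_199",16
"Forest landscape","C3_199",10
"Mangrove Landscape","C3_199",4
"Wetland","C3_199",76
"Estuary","C3_199",0
"Human footprint","C3_3",18050
"Agricultural landscape","C3_3",65424
"Shrubland","C3_3",492409
"Forest landscape","C3_3",197351
"Mangrove Landscape","C3_3",283440
"Wetland","C3_3",46877
"Estuary","C3_3",18632
"Human footprint","C3_4",29601
"Agricultural landscape","C3_4",128003
"Shrubland","C3_4",695661
"Forest landscape","C3_4",302581
"Mangrove Landscape","C3_4",494052
"Wetland","C3_4",91227
"Estuary","C3_4",25831
"Human footprint","C3",57305
"Agricultural landscape","C3",244115
"Shrubland","C3",1257263
"Forest landscape","C3",582424
"Mangrove Landscape","C3",830325
"Wetland","C3",164390
"Estuary","C3",46681
"Human footprint","C4_33",3442
"Agricultural landscape","C4_33",16576
"Shrubland","C4_33",41142
"Forest landscape","C4_33",14174
"Mangrove Landscape","C4_33",48623
"Wetland","C4_33",3514
"Estuary","C4_33",1934
"Human footprint","C4_34",881
"Agricultural landscape","C4_34",3746
"Shrubland","C4_34",8231
"Forest landscape","C4_34",9758
"Mangrove Landscape","C4_34",6306
"Wetland","C4_34",2926
"Estuary","C4_34",265
"Human footprint","C10_1",198885
"Agricultural landscape","C10_1",873072
"Shrubland","C10_1",2236962
"Forest landscape","C10_1",5052486
"Mangrove Landscape","C10_1",4703786
"Wetland","C10_1",601319
"Estuary","C10_1",282179
"Human footprint","C10_2",0.7
"Agricultural landscape","C10_2",0.7
"Shrubland","C10_2",0.81
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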