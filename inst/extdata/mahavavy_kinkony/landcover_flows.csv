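"item","class_name","value"
"opening","Village",433
"opening","Rice field",4256
"opening","Sugar-cane field",4728
"opening","Raffia",959
"opening","Crops field",5817
"opening","Savannah",63937
"opening","Dense dry forest",50031
"opening","Sparse dry forest",42800
"opening","Dense mangrove",6816
"opening","Scattered mangrove",14482
"opening","Stunted mangrove",3047
"opening","Tan",6530
"opening","Shrubland",82737
"opening","Barren land",8391
"opening","Phragmites",2284
"opening","Water bodies",53514
"F_lf1","Village",119
"F_lf1","Rice field",0
"F_lf1","Sugar-cane field",0
"F_lf1","Raffia",0
"F_lf1","Crops field",0
"F_lf1","Savannah",0
"F_lf1","Dense dry forest",0
"F_lf1","Sparse dry forest",0
"F_lf1","Dense mangrove",0
"F_lf1","Scattered mangrove",0
"F_lf1","Stunted mangrove",0
"F_lf1","Tan",0
"F_lf1","Shrubland",0
"F_lf1","Barren land",0
"F_lf1","Phragmites",0
"F_lf1","Water bodies",0
"F_lf2","Village",0
"F_lf2","Rice field",2529
"F_lf2","Sugar-cane field",881
"F_lf2","Raffia",40
"F_lf2","Crops field",8692
"F_lf2","Savannah",1857
"F_lf2","Dense dry forest",0
"F_lf2","Sparse dry forest",0
"F_lf2","Dense mangrove",0
"F_lf2","Scattered mangrove",0
"F_lf2","Stunted mangrove",0
"F_lf2","Tan",0
"F_lf2","Shrubland",0
"F_lf2","Barren land",0
"F_lf2","Phragmites",0
"F_lf2","Water bodies",7
"F_lf3","Village",0
"F_lf3","Rice field",11
"F_lf3","Sugar-cane field",228
"F_lf3","Raffia",0
"F_lf3","Crops field",26
"F_lf3","Savannah",0
"F_lf3","Dense dry forest",7899
"F_lf3","Sparse dry forest",12855
"F_lf3","Dense mangrove",303
"F_lf3","Scattered mangrove",5227
"F_lf3","Stunted mangrove",878
"F_lf3","Tan",521
"F_lf3","Shrubland",0
"F_lf3","Barren land",0
"F_lf3","Phragmites",0
"F_lf3","Water bodies",0
"F_lf4","Village",0
"F_lf4","Rice field",0
"F_lf4","Sugar-cane field",0
"F_lf4","Raffia",0
"F_lf4","Crops field",0
"F_lf4","Savannah",18129
"F_lf4","Dense dry forest",0
"F_lf4","Sparse dry forest",0
"F_lf4","Dense mangrove",0
"F_lf4","Scattered mangrove",0
"F_lf4","Stunted mangrove",0
"F_lf4","Tan",0
"F_lf4","Shrubland",16898
"F_lf4","Barren land",298
"F_lf4","Phragmites",0
"F_lf4","Water bodies",0
"F_lf5","Village",0
"F_lf5","Rice field",0
"F_lf5","Sugar-cane field",0
"F_lf5","Raffia",0
"F_lf5","Crops field",0
"F_lf5","Savannah",165
"F_lf5","Dense dry forest",0
"F_lf5","Sparse dry forest",1837
"F_lf5","Dense mangrove",1
"F_lf5","Scattered mangrove",292
"F_lf5","Stunted mangrove",77
"F_lf5","Tan",1333
"F_lf5","Shrubland",12028
"F_lf5","Barren land",3
"F_lf5","Phragmites",0
"F_lf5","Water bodies",0
"F_lf6","Village",0
"F_lf6","Rice field",0
"F_lf6","Sugar-cane field",0
"F_lf6","Raffia",0
"F_lf6","Crops field",0
"F_lf6","Savannah",0
"F_lf6","Dense dry forest",0
"F_lf6","Sparse dry forest",0
"F_lf6","Dense mangrove",0
"F_lf6","Scattered mangrove",0
"F_lf6","Stunted mangrove",0
"F_lf6","Tan",0
"F_lf6","Shrubland",0
"F_lf6","Barren land",721
"F_lf6","Phragmites",212
"F_lf6","Water bodies",4833
"F_lf7","Village",0
"F_lf7","Rice field",0
"F_lf7","Sugar-cane field",0
"F_lf7","Raffia",0
"F_lf7","Crops field",0
"F_lf7","Savannah",0
"F_lf7","Dense dry forest",0
"F_lf7","Sparse dry forest",0
"F_lf7","Dense mangrove",0
"F_lf7","Scattered mangrove",0
"F_lf7","Stunted mangrove",0
"F_lf7","Tan",0
"F_lf7","Shrubland",0
"F_lf7","Barren land",0
"F_lf7","Phragmites",0
"F_lf7","Water bodies",0
"C_lf1","Village",0
"C_lf1","Rice field",0
"C_lf1","Sugar-cane field",0
"C_lf1","Raffia",0
"C_lf1","Crops field",0
"C_lf1","Savannah",63
"C_lf1","Dense dry forest",0
"C_lf1","Sparse dry forest",38
"C_lf1","Dense mangrove",0
"C_lf1","Scattered mangrove",0
"C_lf1","Stunted mangrove",0
"C_lf1","Tan",0
"C_lf1","Shrubland",17
"C_lf1","Barren land",1
"C_lf1","Phragmites",0
"C_lf1","Water bodies",0
"C_lf2","Village",0
"C_lf2","Rice field",0
"C_lf2","Sugar-cane field",0
"C_lf2","Raffia",0
"C_lf2","Crops field",0
"C_lf2","Savannah",2010
"C_lf2","Dense dry forest",774
"C_lf2","Sparse dry forest",2778
"C_lf2","Dense mangrove",0
"C_lf2","Scattered mangrove",146
"C_lf2","Stunted mangrove",0
"C_lf2","Tan",120
"C_lf2","Shrubland",6136
"C_lf2","Barren land",1198
"C_lf2","Phragmites",548
"C_lf2","Water bodies",296
"C_lf3","Village",0
"C_lf3","Rice field",0
"C_lf3","Sugar-cane field",0
"C_lf3","Raffia",37
"C_lf3","Crops field",228
"C_lf3","Savannah",0
"C_lf3","Dense dry forest",7805
"C_lf3","Sparse dry forest",6255
"C_lf3","Dense mangrove",2189
"C_lf3","Scattered mangrove",802
"C_lf3","Stunted mangrove",1716
"C_lf3","Tan",369
"C_lf3","Shrubland",8547
"C_lf3","Barren land",0
"C_lf3","Phragmites",0
"C_lf3","Water bodies",0
"C_lf4","Village",0
"C_lf4","Rice field",0
"C_lf4","Sugar-cane field",0
"C_lf4","Raffia",0
"C_lf4","Crops field",0
"C_lf4","Savannah",0
"C_lf4","Dense dry forest",2848
"C_lf4","Sparse dry forest",16487
"C_lf4","Dense mangrove",0
"C_lf4","Scattered mangrove",1844
"C_lf4","Stunted mangrove",14
"C_lf4","Tan",2748
"C_lf4","Shrubland",11384
"C_lf4","Barren land",0
"C_lf4","Phragmites",0
"C_lf4","Water bodies",0
"C_lf5","Village",0
"C_lf5","Rice field",0
"C_lf5","Sugar-cane field",0
"C_lf5","Raffia",155
"C_lf5","Crops field",16
"C_lf5","Savannah",13807
"C_lf5","Dense dry forest",0
"C_lf5","Sparse dry forest",0
"C_lf5","Dense mangrove",0
"C_lf5","Scattered mangrove",0
"C_lf5","Stunted mangrove",0
"C_lf5","Tan",0
"C_lf5","Shrubland",0
"C_lf5","Barren land",1096
"C_lf5","Phragmites",320
"C_lf5","Water bodies",342
"C_lf6","Village",0
"C_lf6","Rice field",0
"C_lf6","Sugar-cane field",0
"C_lf6","Raffia",28
"C_lf6","Crops field",2
"C_lf6","Savannah",377
"C_lf6","Dense dry forest",0
"C_lf6","Sparse dry forest",18
"C_lf6","Dense mangrove",1
"C_lf6","Scattered mangrove",236
"C_lf6","Stunted mangrove",53
"C_lf6","Tan",198
"C_lf6","Shrubland",648
"C_lf6","Barren land",3183
"C_lf6","Phragmites",226
"C_lf6","Water bodies",798
"C_lf7","Village",0
"C_lf7","Rice field",0
"C_lf7","Sugar-cane field",0
"C_lf7","Raffia",0
"C_lf7","Crops field",0
"C_lf7","Savannah",0
"C_lf7","Dense dry forest",0
"C_lf7","Sparse dry forest",0
"C_lf7","Dense mangrove",0
"C_lf7","Scattered mangrove",0
"C_lf7","Stunted mangrove",0
"C_lf7","Tan",0
"C_lf7","Shrubland",0
"C_lf7","Barren land",0
"C_lf7","Phragmites",0
"C_lf7","Water bodies",0
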