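"gene","atypical","basal","classical","mesenchymal"
"GENE0001",0.5472,-0.7591,1.7882,0.9859
"GENE0002",-0.0794,-0.1536,1.1295,0.3519
"GENE0003",-1.8062,0.2935,-0.2325,1.5241
"GENE0004",0.4678,0.4481,0.4142,-0.1053
"GENE0005",0.1869,-0.3662,-1.163,-1.1041
"GENE0006",-0.546,0.0036,0.5954,0.7147
"GENE0007",-0.3416,-1.0052,0.5822,0.5314
"GENE0008",0.5238,0.6046,-1.0497,-0.2463
"GENE0009",1.3519,-1.5188,0.1283,0.8861
"GENE0010",-1.5568,1.2937,-1.4386,1.2722
"GENE0011",0.6123,-0.3598,-0.796,0.8036
"GENE0012",0.0542,-0.155,-1.1396,0.185
"GENE0013",0.7801,-1.5436,-0.318,-1.4149
"GENE0014",-1.1099,-0.1651,-2.5481,0.3722
"GENE0015",0.2479,0.5678,-0.1759,0.2282
"GENE0016",1.5875,0.266,-0.6363,-0.1686
"GENE0017",-1.8904,-0.3359,0.2396,1.0244
"GENE0018",-0.089,-0.2091,-0.2036,0.3604
"GENE0019",-1.1425,0.2151,-0.584,-0.4365
"GENE0020",2.275,0.8089,-0.9087,-1.632
"GENE0021",0.2272,0.6295,-0.4317,1.7284
"GENE0022",0.2071,-0.2191,-0.0095,-0.1154
"GENE0023",-0.6927,-0.65,-1.6104,-2.0561
"GENE0024",-0.5883,-0.6862,-0.2019,-2.5657
"GENE0025",-1.2641,-0.0099,0.9994,-0.3486
"GENE0026",0.5274,0.0102,0.8162,0.0047
"GENE0027",-0.5127,-1.2802,0.3733,-0.2906
"GENE0028",0.4999,-0.1861,-0.682,-0.2069
"GENE0029",-1.1495,0.3847,0.7123,1.4771
"GENE0030",0.1921,-2.1095,-0.7849,-0.7322
"GENE0031",0.404,-0.583,-0.5834,-0.7036
"GENE0032",-0.3865,0.5161,-0.3032,1.3434
"GENE0033",1.2787,0.1706,0.8142,0.4521
"GENE0034",0.6809,-0.1772,0.6665,1.0415
"GENE0035",-0.4363,0.5173,-0.0611,-0.072
"GENE0036",0.8477,-0.8891,2.1164,0.2165
"GENE0037",-0.7489,0.4026,-0.9764,-0.4179
"GENE0038",-0.3959,0.6362,1.4101,-0.3677
"GENE0039",-1.0574,-1.6341,1.0451,1.496
"GENE0040",-0.8947,-0.6625,-0.1892,-0.1742
"GENE0041",0.2115,-0.5637,-0.0134,-1.4353
"GENE0042",-1.085,-0.2722,0.0994,0.104
"GENE0043",0.5869,0.3717,-0.0632,-0.2327
"GENE0044",-1.012,0.7146,-1.13,1.18
"GENE0045",1.2064,0.7868,-0.946,-0.6187
"GENE0046",-1.0474,1.0895,0.086,0.3908
"GENE0047",-1.0934,-0.5712,1.6925,-0.0529
"GENE0048",0.1671,-1.633,1.1977,-0.4022
"GENE0049",-1.2694,1.5537,-2.7839,0.4142
"GENE0050",0.0995,-0.1609,0.4144,-0.9764
"GENE0051",-1.1316,-0.0698,2.9209,0.7375
"GENE0052",0.6624,-0.2482,-0.0226,-0.73
"GENE0053",0.2093,0.2248,-1.0546,-1.2459
"GENE0054",-0.3229,0.599,-1.3953,0.0592
"GENE0055",0.8557,1.0052,1.2237,0.4331
"GENE0056",0.2798,-2.3339,-1.9303,1.6101
"GENE0057",1.7116,1.0373,-0.1883,1.0198
"GENE0058",-0.4296,0.2904,-2.2134,1.2245
"GENE0059",-1.8608,-1.9163,0.2223,1.4589
"GENE0060",-0.612,0.759,1.5569,-0.9873
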