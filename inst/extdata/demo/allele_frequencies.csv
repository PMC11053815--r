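# synthetic demo allele frequencies (generated, not IEDB data)
"region","locus","allele","frequency"
"World","A","HLA-A*01:01",0.03262
"World","A","HLA-A*02:01",0.047039
"World","A","HLA-A*02:03",0.053518
"World","A","HLA-A*02:06",0.090652
"World","A","HLA-A*03:01",0.046382
"World","A","HLA-A*11:01",0.007114
"World","A","HLA-A*23:01",0.127785
"World","A","HLA-A*24:02",0.065646
"World","A","HLA-A*26:01",0.044535
"World","A","HLA-A*30:01",0.013927
"World","A","HLA-A*30:02",0.093682
"World","A","HLA-A*31:01",0.028542
"World","A","HLA-A*32:01",0.020886
"World","A","HLA-A*33:01",0.024497
"World","A","HLA-A*68:01",0.013488
"World","A","HLA-A*68:02",0.010509
"World","B","HLA-B*07:02",0.130049
"World","B","HLA-B*08:01",0.06256
"World","B","HLA-B*15:01",0.001235
"World","B","HLA-B*35:01",0.186485
"World","B","HLA-B*40:01",0.053818
"World","B","HLA-B*44:02",0.114837
"World","B","HLA-B*44:03",0.072869
"World","B","HLA-B*51:01",0.020574
"World","B","HLA-B*53:01",0.099835
"World","B","HLA-B*57:01",0.085935
"World","B","HLA-B*58:01",0.056925
"World","DR","HLA-DRB1*01:01",0.048588
"World","DR","HLA-DRB1*03:01",0.032406
"World","DR","HLA-DRB1*04:01",0.021754
"World","DR","HLA-DRB1*04:05",0.021603
"World","DR","HLA-DRB1*07:01",0.01893
"World","DR","HLA-DRB1*08:02",0.022173
"World","DR","HLA-DRB1*09:01",0.012509
"World","DR","HLA-DRB1*11:01",0.062543
"World","DR","HLA-DRB1*12:01",0.03751
"World","DR","HLA-DRB1*13:02",0.074883
"World","DR","HLA-DRB1*15:01",0.087971
"World","DR","HLA-DRB3*01:01",0.028962
"World","DR","HLA-DRB3*02:02",0.006115
"World","DR","HLA-DRB4*01:01",0.10924
"World","DR","HLA-DRB5*01:01",0.027908
"World","DP","HLA-DPA1*01:03/DPB1*02:01",0.232796
"World","DP","HLA-DPA1*01:03/DPB1*04:01",0.186881
"World","DP","HLA-DPA1*02:01/DPB1*01:01",0.077453
"World","DP","HLA-DPA1*02:01/DPB1*05:01",0.089681
"World","DP","HLA-DPA1*02:01/DPB1*14:01",0.04149
"World","DP","HLA-DPA1*03:01/DPB1*04:02",0.005574
"World","DQ","HLA-DQA1*01:01/DQB1*05:01",0.077439
"World","DQ","HLA-DQA1*01:02/DQB1*06:02",0.212568
"World","DQ","HLA-DQA1*03:01/DQB1*03:02",0.155011
"World","DQ","HLA-DQA1*04:01/DQB1*04:02",0.174507
"World","DQ","HLA-DQA1*05:01/DQB1*02:01",0.066557
"World","DQ","HLA-DQA1*05:01/DQB1*03:01",0.052974
"Region01","A","HLA-A*01:01",0.00622
"Region01","A","HLA-A*02:01",0.095697
"Region01","A","HLA-A*02:03",0.042327
"Region01","A","HLA-A*02:06",0.051683
"Region01","A","HLA-A*03:01",0.026249
"Region01","A","HLA-A*11:01",0.038911
"Region01","A","HLA-A*23:01",0.152759
"Region01","A","HLA-A*24:02",0.027144
"Region01","A","HLA-A*26:01",0.035791
"Region01","A","HLA-A*30:01",0.017025
"Region01","A","HLA-A*30:02",0.078519
"Region01","A","HLA-A*31:01",0.075931
"Region01","A","HLA-A*32:01",0.037876
"Region01","A","HLA-A*33:01",0.07819
"Region01","A","HLA-A*68:01",0.008168
"Region01","A","HLA-A*68:02",0.084369
"Region01","B","HLA-B*07:02",0.142288
"Region01","B","HLA-B*08:01",0.078132
"Region01","B","HLA-B*15:01",0.068871
"Region01","B","HLA-B*35:01",0.116646
"Region01","B","HLA-B*40:01",0.039432
"Region01","B","HLA-B*44:02",0.091098
"Region01","B","HLA-B*44:03",0.037007
"Region01","B","HLA-B*51:01",0.042763
"Region01","B","HLA-B*53:01",0.048531
"Region01","B","HLA-B*57:01",0.045198
"Region01","B","HLA-B*58:01",0.063642
"Region01","DR","HLA-DRB1*01:01",0.039581
"Region01","DR","HLA-DRB1*03:01",0.041238
"Region01","DR","HLA-DRB1*04:01",0.071088
"Region01","DR","HLA-DRB1*04:05",0.001802
"Region01","DR","HLA-DRB1*07:01",0.003984
"Region01","DR","HLA-DRB1*08:02",0.046214
"Region01","DR","HLA-DRB1*09:01",0.111653
"Region01","DR","HLA-DRB1*11:01",0.009515
"Region01","DR","HLA-DRB1*12:01",0.021085
"Region01","DR","HLA-DRB1*13:02",0.0465
"Region01","DR","HLA-DRB1*15:01",0.027329
"Region01","DR","HLA-DRB3*01:01",0.045759
"Region01","DR","HLA-DRB3*02:02",0.082409
"Region01","DR","HLA-DRB4*01:01",0.036299
"Region01","DR","HLA-DRB5*01:01",0.043287
"Region01","DP","HLA-DPA1*01:03/DPB1*02:01",0.009014
"Region01","DP","HLA-DPA1*01:03/DPB1*04:01",0.238661
"Region01","DP","HLA-DPA1*02:01/DPB1*01:01",0.104482
"Region01","DP","HLA-DPA1*02:01/DPB1*05:01",0.063104
"Region01","DP","HLA-DPA1*02:01/DPB1*14:01",0.074766
"Region01","DP","HLA-DPA1*03:01/DPB1*04:02",0.151404
"Region01","DQ","HLA-DQA1*01:01/DQB1*05:01",0.039497
"Region01","DQ","HLA-DQA1*01:02/DQB1*06:02",0.063588
"Region01","DQ","HLA-DQA1*03:01/DQB1*03:02",0.376321
"Region01","DQ","HLA-DQA1*04:01/DQB1*04:02",0.166667
"Region01","DQ","HLA-DQA1*05:01/DQB1*02:01",0.028292
"Region01","DQ","HLA-DQA1*05:01/DQB1*03:01",0.04875
"Region02","A","HLA-A*01:01",0.024096
"Region02","A","HLA-A*02:01",0.024173
"Region02","A","HLA-A*02:03",0.014037
"Region02","A","HLA-A*02:06",0.09307
"Region02","A","HLA-A*03:01",0.054286
"Region02","A","HLA-A*11:01",0.02267
"Region02","A","HLA-A*23:01",0.069795
"Region02","A","HLA-A*24:02",0.01663
"Region02","A","HLA-A*26:01",0.010697
"Region02","A","HLA-A*30:01",0.065951
"Region02","A","HLA-A*30:02",0.009438
"Region02","A","HLA-A*31:01",0.040459
"Region02","A","HLA-A*32:01",0.124855
"Region02","A","HLA-A*33:01",0.008376
"Region02","A","HLA-A*68:01",0.02215
"Region02","A","HLA-A*68:02",0.062138
"Region02","B","HLA-B*07:02",0.087776
"Region02","B","HLA-B*08:01",0.111276
"Region02","B","HLA-B*15:01",0.079638
"Region02","B","HLA-B*35:01",0.153703
"Region02","B","HLA-B*40:01",0.03222
"Region02","B","HLA-B*44:02",0.043741
"Region02","B","HLA-B*44:03",0.116238
"Region02","B","HLA-B*51:01",0.043789
"Region02","B","HLA-B*53:01",0.083274
"Region02","B","HLA-B*57:01",0.064891
"Region02","B","HLA-B*58:01",0.101762
"Region02","DR","HLA-DRB1*01:01",0.091312
"Region02","DR","HLA-DRB1*03:01",0.015685
"Region02","DR","HLA-DRB1*04:01",0.086629
"Region02","DR","HLA-DRB1*04:05",0.00831
"Region02","DR","HLA-DRB1*07:01",0.025823
"Region02","DR","HLA-DRB1*08:02",0.087278
"Region02","DR","HLA-DRB1*09:01",0.030632
"Region02","DR","HLA-DRB1*11:01",0.04276
"Region02","DR","HLA-DRB1*12:01",0.096304
"Region02","DR","HLA-DRB1*13:02",0.005101
"Region02","DR","HLA-DRB1*15:01",0.062071
"Region02","DR","HLA-DRB3*01:01",0.069703
"Region02","DR","HLA-DRB3*02:02",0.024194
"Region02","DR","HLA-DRB4*01:01",0.095079
"Region02","DR","HLA-DRB5*01:01",0.012406
"Region02","DP","HLA-DPA1*01:03/DPB1*02:01",0.237063
"Region02","DP","HLA-DPA1*01:03/DPB1*04:01",0.21554
"Region02","DP","HLA-DPA1*02:01/DPB1*01:01",0.071043
"Region02","DP","HLA-DPA1*02:01/DPB1*05:01",0.145418
"Region02","DP","HLA-DPA1*02:01/DPB1*14:01",0.089944
"Region02","DP","HLA-DPA1*03:01/DPB1*04:02",0.125112
"Region02","DQ","HLA-DQA1*01:01/DQB1*05:01",0.268713
"Region02","DQ","HLA-DQA1*01:02/DQB1*06:02",0.089023
"Region02","DQ","HLA-DQA1*03:01/DQB1*03:02",0.100607
"Region02","DQ","HLA-DQA1*04:01/DQB1*04:02",0.107159
"Region02","DQ","HLA-DQA1*05:01/DQB1*02:01",0.055262
"Region02","DQ","HLA-DQA1*05:01/DQB1*03:01",0.056492
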