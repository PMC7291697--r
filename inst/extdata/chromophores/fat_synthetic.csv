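wavelength_nm,specific_absorption
450,0.012
452,0.01192
454,0.01184
456,0.01176
458,0.01168
460,0.0116
462,0.01152
464,0.01144
466,0.01136
468,0.01128
470,0.0112
472,0.01112
474,0.01104
476,0.01096
478,0.01088
480,0.0108
482,0.01072
484,0.01064
486,0.01056
488,0.01048
490,0.0104
492,0.01032
494,0.01024
496,0.01016
498,0.01008
500,0.01
502,0.00992
504,0.00984
506,0.00976
508,0.00968
510,0.0096
512,0.00952
514,0.00944
516,0.00936
518,0.00928
520,0.0092
522,0.00912
524,0.00904
526,0.00896
528,0.00888
530,0.0088
532,0.00872
534,0.00864
536,0.00856
538,0.00848
540,0.0084
542,0.00832
544,0.00824
546,0.00816
548,0.00808
550,0.008
552,0.00791923
554,0.00783706
556,0.00775366
558,0.00766925
560,0.007584
562,0.00749811
564,0.00741178
566,0.00732518
568,0.00723853
570,0.007152
572,0.00706579
574,0.0069801
576,0.0068951
578,0.00681101
580,0.006728
582,0.00664627
584,0.00656602
586,0.00648742
588,0.00641069
590,0.006336
592,0.00626355
594,0.00619354
596,0.00612614
598,0.00606157
600,0.006
602,0.00594003
604,0.00588026
606,0.00582086
608,0.00576205
610,0.005704
612,0.00564691
614,0.00559098
616,0.00553638
618,0.00548333
620,0.005432
622,0.00538259
624,0.0053353
626,0.0052903
628,0.00524781
630,0.005208
632,0.00517107
634,0.00513722
636,0.00510662
638,0.00507949
640,0.005056
642,0.00503635
644,0.00502074
646,0.00500934
648,0.00500237
650,0.005
652,0.00500237
654,0.00500934
656,0.00502074
658,0.00503635
660,0.005056
662,0.00507949
664,0.00510662
666,0.00513722
668,0.00517107
670,0.005208
672,0.00524781
674,0.0052903
676,0.0053353
678,0.00538259
680,0.005432
682,0.00548333
684,0.00553638
686,0.00559098
688,0.00564691
690,0.005704
692,0.00576205
694,0.00582086
696,0.00588026
698,0.00594003
700,0.006
702,0.00606234
704,0.00612909
706,0.00619987
708,0.0062743
710,0.006352
712,0.00643258
714,0.00651565
716,0.00660083
718,0.00668774
720,0.006776
722,0.00686522
724,0.00695501
726,0.00704499
728,0.00713478
730,0.007224
732,0.00731226
734,0.00739917
736,0.00748435
738,0.00756742
740,0.007648
742,0.0077257
744,0.00780013
746,0.00787091
748,0.00793766
750,0.008
752,0.0080569
754,0.00810797
756,0.00815379
758,0.00819494
760,0.008232
762,0.00826554
764,0.00829613
766,0.00832435
768,0.00835078
770,0.008376
772,0.00840058
774,0.00842509
776,0.00845011
778,0.00847622
780,0.008504
782,0.00853402
784,0.00856685
786,0.00860307
788,0.00864326
790,0.008688
792,0.00873786
794,0.00879341
796,0.00885523
798,0.0089239
800,0.009
802,0.00908158
804,0.00916632
806,0.00925423
808,0.00934532
810,0.00943958
812,0.00953703
814,0.00963766
816,0.00974149
818,0.00984852
820,0.00995875
822,0.0100722
824,0.0101888
826,0.0103087
828,0.0104318
830,0.0105581
832,0.0106877
834,0.0108205
836,0.0109565
838,0.0110958
840,0.0112383
842,0.0113841
844,0.0115332
846,0.0116855
848,0.0118411
850,0.012
852,0.0121491
854,0.0122796
856,0.012398
858,0.0125108
860,0.0126243
862,0.0127451
864,0.0128796
866,0.0130342
868,0.0132154
870,0.0134298
872,0.0136836
874,0.0139834
876,0.0143356
878,0.0147467
880,0.0152231
882,0.0157713
884,0.0163977
886,0.0171088
888,0.0179111
890,0.0188109
892,0.0198148
894,0.0209292
896,0.0221606
898,0.0235154
900,0.025
902,0.0274139
904,0.0313844
906,0.0366593
908,0.0429868
910,0.0501149
912,0.0577917
914,0.0657652
916,0.0737834
918,0.0815945
920,0.0889464
922,0.0955871
924,0.101265
926,0.105728
928,0.108723
930,0.11
932,0.10914
934,0.106187
936,0.10158
938,0.09576
940,0.0891667
942,0.08224
944,0.07542
946,0.0691467
948,0.06386
950,0.06
952,0.05738
954,0.05544
956,0.05406
958,0.05312
960,0.0525
962,0.05208
964,0.05174
966,0.05136
968,0.05082
970,0.05
972,0.04893
974,0.04774
976,0.04646
978,0.04512
980,0.04375
982,0.04238
984,0.04104
986,0.03976
988,0.03857
990,0.0375
992,0.03658
994,0.03584
996,0.03531
998,0.03502
1000,0.035
1002,0.0352802
1004,0.03585
1006,0.0366781
1008,0.0377333
1010,0.0389844
1012,0.0404
1014,0.041949
1016,0.0436
1018,0.0453219
1020,0.0470833
1022,0.0488531
1024,0.0506
1026,0.0522927
1028,0.0539
1030,0.0553906
1032,0.0567333
1034,0.0578969
1036,0.05885
1038,0.0595615
1040,0.06
1042,0.060115
1044,0.0598966
1046,0.0593748
1048,0.0585794
1050,0.0575405
1052,0.056288
1054,0.0548518
1056,0.0532619
1058,0.0515483
1060,0.0497407
1062,0.0478693
1064,0.045964
1066,0.0440547
1068,0.0421713
1070,0.0403438
1072,0.0386021
1074,0.0369762
1076,0.035496
1078,0.0341915
1080,0.0330926
1082,0.0322292
1084,0.0316314
1086,0.031329
1088,0.031352
1090,0.0317303
1092,0.0324939
1094,0.0336728
1096,0.0352967
1098,0.0373958
1100,0.04
1102,0.0429466
1104,0.0460631
1106,0.0493651
1108,0.0528678
1110,0.0565867
1112,0.060537
1114,0.0647341
1116,0.0691934
1118,0.0739302
1120,0.07896
1122,0.084298
1124,0.0899597
1126,0.0959603
1128,0.102315
1130,0.10904
1132,0.11615
1134,0.12366
1136,0.131586
1138,0.139943
1140,0.148747
1142,0.158012
1144,0.167755
1146,0.17799
1148,0.188733
1150,0.2
1152,0.211573
1154,0.223311
1156,0.235344
1158,0.247802
1160,0.260815
1162,0.274512
1164,0.289023
1166,0.304479
1168,0.321008
1170,0.338741
1172,0.357807
1174,0.378336
1176,0.400458
1178,0.424303
1180,0.45
1182,0.480496
1184,0.517748
1186,0.5604
1188,0.607096
1190,0.656481
1192,0.7072
1194,0.757896
1196,0.807215
1198,0.8538
1200,0.896296
1202,0.933348
1204,0.9636
1206,0.985696
1208,0.998281
1210,1
1212,0.986972
1214,0.958347
1216,0.917308
1218,0.86704
1220,0.810729
1222,0.75156
1224,0.692718
1226,0.637387
1228,0.588753
1230,0.55
1232,0.517847
1234,0.48689
1236,0.457136
1238,0.428588
1240,0.401252
1242,0.375132
1244,0.350235
1246,0.326563
1248,0.304124
1250,0.282921
1252,0.26296
1254,0.244245
1256,0.226782
1258,0.210575
1260,0.19563
1262,0.181951
1264,0.169544
1266,0.158413
1268,0.148563
1270,0.14
1272,0.132522
1274,0.125898
1276,0.12009
1278,0.115059
1280,0.110767
1282,0.107175
1284,0.104246
1286,0.101939
1288,0.100216
1290,0.0990402
1292,0.0983714
1294,0.0981716
1296,0.0984021
1298,0.0990244
1300,0.1
1302,0.101348
1304,0.103109
1306,0.105282
1308,0.107862
1310,0.110846
1312,0.11423
1314,0.118011
1316,0.122186
1318,0.12675
1320,0.131702
1322,0.137036
1324,0.14275
1326,0.14884
1328,0.155302
1330,0.162134
1332,0.169332
1334,0.176892
1336,0.184811
1338,0.193085
1340,0.201711
1342,0.210686
1344,0.220006
1346,0.229667
1348,0.239666
1350,0.25
1352,0.260915
1354,0.27262
1356,0.285055
1358,0.29816
1360,0.311875
1362,0.32614
1364,0.340895
1366,0.35608
1368,0.371635
1370,0.3875
1372,0.403615
1374,0.41992
1376,0.436355
1378,0.45286
1380,0.469375
1382,0.48584
1384,0.502195
1386,0.51838
1388,0.534335
1390,0.55
1392,0.566481
1394,0.584597
1396,0.603856
1398,0.623769
1400,0.643843
1402,0.663588
1404,0.682513
1406,0.700127
1408,0.715938
1410,0.729457
1412,0.740192
1414,0.747652
1416,0.751529
1418,0.752702
1420,0.751539
1422,0.748256
1424,0.743067
1426,0.736187
1428,0.727832
1430,0.718216
1432,0.707554
1434,0.696061
1436,0.683952
1438,0.671442
1440,0.658746
1442,0.646079
1444,0.633656
1446,0.621692
1448,0.610402
1450,0.6
1452,0.589888
1454,0.579354
1456,0.56844
1458,0.557189
1460,0.545646
1462,0.533853
1464,0.521853
1466,0.509691
1468,0.497409
1470,0.485051
1472,0.47266
1474,0.46028
1476,0.447953
1478,0.435724
1480,0.423634
1482,0.411729
1484,0.40005
1486,0.388643
1488,0.377548
1490,0.366811
1492,0.356475
1494,0.346582
1496,0.337177
1498,0.328301
1500,0.32
1502,0.312174
1504,0.304689
1506,0.297532
1508,0.290693
1510,0.28416
1512,0.277921
1514,0.271965
1516,0.266281
1518,0.260856
1520,0.25568
1522,0.25074
1524,0.246026
1526,0.241526
1528,0.237228
1530,0.23312
1532,0.229192
1534,0.225431
1536,0.221827
1538,0.218367
1540,0.21504
1542,0.211835
1544,0.20874
1546,0.205743
1548,0.202834
1550,0.2
1552,0.197357
1554,0.195014
1556,0.192954
1558,0.191155
1560,0.1896
1562,0.188269
1564,0.187142
1566,0.186202
1568,0.185427
1570,0.1848
1572,0.184301
1574,0.18391
1576,0.18361
1578,0.183379
1580,0.1832
1582,0.183053
1584,0.182918
1586,0.182778
1588,0.182611
1590,0.1824
1592,0.182125
1594,0.181766
1596,0.181306
1598,0.180723
1600,0.18
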