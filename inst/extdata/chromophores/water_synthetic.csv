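wavelength_nm,specific_absorption
450,3e-04
452,0.000297811
454,0.000295277
456,0.000292444
458,0.000289359
460,0.00028607
462,0.000282623
464,0.000279067
466,0.000275447
468,0.000271812
470,0.000268209
472,0.000264684
474,0.000261285
476,0.000258058
478,0.000255052
480,0.000252313
482,0.000249889
484,0.000247826
486,0.000246172
488,0.000244974
490,0.000244278
492,0.000244134
494,0.000244586
496,0.000245683
498,0.000247472
500,0.00025
502,0.000252706
504,0.00025508
506,0.000257244
508,0.000259322
510,0.000261435
512,0.000263706
514,0.000266259
516,0.000269215
518,0.000272696
520,0.000276827
522,0.000281729
524,0.000287525
526,0.000294337
528,0.000302288
530,0.000311502
532,0.000322099
534,0.000334203
536,0.000347937
538,0.000363423
540,0.000380784
542,0.000400142
544,0.00042162
546,0.000445341
548,0.000471427
550,5e-04
552,0.000533853
554,0.000575312
556,0.000623799
558,0.000678736
560,0.000739546
562,0.000805653
564,0.000876478
566,0.000951444
568,0.00102997
570,0.00111149
572,0.00119541
574,0.00128117
576,0.00136818
578,0.00145587
580,0.00154366
582,0.00163097
584,0.00171723
586,0.00180185
588,0.00188426
590,0.00196389
592,0.00204015
594,0.00211247
596,0.00218027
598,0.00224297
600,0.0023
602,0.0023519
604,0.00239985
606,0.00244417
608,0.00248522
610,0.00252334
612,0.00255888
614,0.00259217
616,0.00262356
618,0.0026534
620,0.00268203
622,0.00270979
624,0.00273703
626,0.00276408
628,0.00279131
630,0.00281904
632,0.00284762
634,0.00287741
636,0.00290873
638,0.00294193
640,0.00297737
642,0.00301538
644,0.0030563
646,0.00310048
648,0.00314827
650,0.0032
652,0.00324995
654,0.00329318
656,0.00333125
658,0.00336571
660,0.0033981
662,0.00342998
664,0.0034629
666,0.0034984
668,0.00353804
670,0.00358337
672,0.00363594
674,0.0036973
676,0.00376899
678,0.00385257
680,0.00394959
682,0.0040616
684,0.00419015
686,0.00433679
688,0.00450307
690,0.00469054
692,0.00490075
694,0.00513525
696,0.00539559
698,0.00568333
700,0.006
702,0.00639991
704,0.00692573
706,0.00756159
708,0.00829163
710,0.00909999
712,0.00997079
714,0.0108882
716,0.0118363
718,0.0127992
720,0.0137611
722,0.0147061
724,0.0156184
726,0.016482
728,0.0172812
730,0.018
732,0.0186843
734,0.0193849
736,0.0200936
738,0.020802
740,0.0215019
742,0.0221848
744,0.0228425
746,0.0234668
748,0.0240492
750,0.0245815
752,0.0250553
754,0.0254624
756,0.0257944
758,0.0260431
760,0.0262
762,0.0262352
764,0.0261351
766,0.0259157
768,0.0255932
770,0.0251838
772,0.0247036
774,0.0241688
776,0.0235955
778,0.023
780,0.0223983
782,0.0218067
784,0.0212413
786,0.0207182
788,0.0202536
790,0.0198638
792,0.0195647
794,0.0193726
796,0.0193037
798,0.0193741
800,0.0196
802,0.0199584
804,0.0204117
806,0.0209538
808,0.0215788
810,0.0222808
812,0.0230538
814,0.0238918
816,0.0247889
818,0.0257391
820,0.0267364
822,0.0277749
824,0.0288487
826,0.0299517
828,0.031078
830,0.0322216
832,0.0333766
834,0.034537
836,0.0356969
838,0.0368503
840,0.0379912
842,0.0391137
844,0.0402117
846,0.0412795
848,0.0423109
850,0.0433
852,0.0442004
854,0.0449807
856,0.0456575
858,0.0462473
860,0.0467667
862,0.0472323
864,0.0476606
866,0.0480683
868,0.0484719
870,0.048888
872,0.0493332
874,0.049824
876,0.050377
878,0.0510088
880,0.051736
882,0.0525751
884,0.0535428
886,0.0546556
888,0.05593
890,0.0573827
892,0.0590302
894,0.0608891
896,0.062976
898,0.0653074
900,0.0679
902,0.0706038
904,0.0732983
906,0.0760438
908,0.078901
910,0.0819304
912,0.0851923
914,0.0887474
916,0.0926561
918,0.0969789
920,0.101776
922,0.107109
924,0.113037
926,0.119621
928,0.126922
930,0.135
932,0.143957
934,0.153823
936,0.164553
938,0.176101
940,0.188421
942,0.201467
944,0.215194
946,0.229556
948,0.244506
950,0.26
952,0.277484
954,0.297808
956,0.320034
958,0.343224
960,0.366438
962,0.388736
964,0.40918
966,0.426832
968,0.440752
970,0.45
972,0.45516
974,0.457617
976,0.457632
978,0.455468
980,0.451389
982,0.445656
984,0.438532
986,0.430281
988,0.421164
990,0.411444
992,0.401385
994,0.391248
996,0.381296
998,0.371793
1000,0.363
1002,0.354107
1004,0.344215
1006,0.333456
1008,0.32196
1010,0.309859
1012,0.297285
1014,0.284368
1016,0.27124
1018,0.258032
1020,0.244875
1022,0.231901
1024,0.21924
1026,0.207024
1028,0.195385
1030,0.184453
1032,0.17436
1034,0.165237
1036,0.157215
1038,0.150426
1040,0.145
1042,0.140499
1044,0.136396
1046,0.132692
1048,0.129391
1050,0.126493
1052,0.124
1054,0.121914
1056,0.120236
1058,0.118968
1060,0.118111
1062,0.117668
1064,0.11764
1066,0.118029
1068,0.118836
1070,0.120062
1072,0.121711
1074,0.123783
1076,0.12628
1078,0.129204
1080,0.132556
1082,0.136338
1084,0.140551
1086,0.145198
1088,0.15028
1090,0.155799
1092,0.161756
1094,0.168153
1096,0.174991
1098,0.182273
1100,0.19
1102,0.198356
1104,0.207499
1106,0.217392
1108,0.227998
1110,0.23928
1112,0.251201
1114,0.263725
1116,0.276814
1118,0.290431
1120,0.30454
1122,0.319103
1124,0.334084
1126,0.349444
1128,0.365149
1130,0.38116
1132,0.397441
1134,0.413954
1136,0.430663
1138,0.447531
1140,0.46452
1142,0.481594
1144,0.498716
1146,0.515849
1148,0.532956
1150,0.55
1152,0.567672
1154,0.586595
1156,0.606625
1158,0.62762
1160,0.64944
1162,0.671941
1164,0.694982
1166,0.71842
1168,0.742113
1170,0.76592
1172,0.789698
1174,0.813305
1176,0.836599
1178,0.859438
1180,0.88168
1182,0.903183
1184,0.923804
1186,0.943402
1188,0.961835
1190,0.97896
1192,0.994636
1194,1.00872
1196,1.02107
1198,1.03154
1200,1.04
1202,1.04602
1204,1.04943
1206,1.05046
1208,1.04932
1210,1.04624
1212,1.04144
1214,1.03515
1216,1.02758
1218,1.01896
1220,1.00952
1222,0.999471
1224,0.989039
1226,0.978449
1228,0.967921
1230,0.95768
1232,0.947948
1234,0.938947
1236,0.9309
1238,0.92403
1240,0.91856
1242,0.914712
1244,0.91271
1246,0.912775
1248,0.915131
1250,0.92
1252,0.926125
1254,0.932188
1256,0.938315
1258,0.944636
1260,0.95128
1262,0.958375
1264,0.96605
1266,0.974433
1268,0.983654
1270,0.99384
1272,1.00512
1274,1.01762
1276,1.03148
1278,1.04682
1280,1.06376
1282,1.08244
1284,1.10299
1286,1.12553
1288,1.1502
1290,1.17712
1292,1.20642
1294,1.23823
1296,1.27268
1298,1.30989
1300,1.35
1302,1.38787
1304,1.41906
1306,1.44474
1308,1.46611
1310,1.48432
1312,1.50056
1314,1.51601
1316,1.53184
1318,1.54923
1320,1.56936
1322,1.5934
1324,1.62253
1326,1.65793
1328,1.70078
1330,1.75224
1332,1.8135
1334,1.88574
1336,1.97013
1338,2.06785
1340,2.18008
1342,2.30799
1344,2.45276
1346,2.61557
1348,2.79759
1350,3
1352,3.21853
1354,3.4482
1356,3.68907
1358,3.94124
1360,4.2048
1362,4.47983
1364,4.76642
1366,5.06465
1368,5.37462
1370,5.6964
1372,6.03009
1374,6.37576
1376,6.73352
1378,7.10343
1380,7.4856
1382,7.8801
1384,8.28703
1386,8.70646
1388,9.13849
1390,9.5832
1392,10.0407
1394,10.511
1396,10.9943
1398,11.4906
1400,12
1402,12.5475
1404,13.1538
1406,13.8126
1408,14.5176
1410,15.2624
1412,16.0408
1414,16.8463
1416,17.6728
1418,18.5139
1420,19.3632
1422,20.2145
1424,21.0614
1426,21.8976
1428,22.7169
1430,23.5128
1432,24.2791
1434,25.0094
1436,25.6975
1438,26.337
1440,26.9216
1442,27.445
1444,27.9008
1446,28.2828
1448,28.5847
1450,28.8
1452,28.9319
1454,28.9908
1456,28.981
1458,28.9071
1460,28.7736
1462,28.5849
1464,28.3456
1466,28.0602
1468,27.7331
1470,27.3688
1472,26.9719
1474,26.5467
1476,26.0979
1478,25.6299
1480,25.1472
1482,24.6543
1484,24.1557
1486,23.6558
1488,23.1592
1490,22.6704
1492,22.1938
1494,21.734
1496,21.2954
1498,20.8826
1500,20.5
1502,20.1266
1504,19.7393
1506,19.3397
1508,18.9293
1510,18.5096
1512,18.0821
1514,17.6484
1516,17.2099
1518,16.7682
1520,16.3248
1522,15.8812
1524,15.4389
1526,14.9995
1528,14.5644
1530,14.1352
1532,13.7134
1534,13.3005
1536,12.898
1538,12.5075
1540,12.1304
1542,11.7683
1544,11.4227
1546,11.0951
1548,10.787
1550,10.5
1552,10.2337
1554,9.98609
1556,9.75592
1558,9.54202
1560,9.3432
1562,9.15827
1564,8.98603
1566,8.8253
1568,8.67489
1570,8.5336
1572,8.40025
1574,8.27364
1576,8.1526
1578,8.03591
1580,7.9224
1582,7.81087
1584,7.70014
1586,7.58901
1588,7.47629
1590,7.3608
1592,7.24134
1594,7.11672
1596,6.98575
1598,6.84724
1600,6.7
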