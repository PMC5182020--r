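element,energy_kev,photoelectric,incoherent,coherent
H,1,2.67545,0.104022,1.95014
H,1.5,0.80896,0.179509,0.902593
H,2,0.346225,0.229169,0.522527
H,3,0.104686,0.285143,0.241844
H,4,0.0448043,0.313919,0.140008
H,5,0.0231972,0.330577,0.0916268
H,6,0.0135472,0.340993,0.0648004
H,8,0.00579804,0.352471,0.0375141
H,10,0.0030019,0.357847,0.0245508
H,12,0.00175312,0.360295,0.0173628
H,15,0.000907668,0.361195,0.011363
H,20,0.00038847,0.359298,0.00657822
H,25,0.000201128,0.355634,0.00430506
H,30,0.00011746,0.351277,0.00304463
H,40,5.02712e-05,0.341959,0.00176259
H,50,2.60276e-05,0.332702,0.00115351
H,60,1.52002e-05,0.323853,0.000815789
H,80,6.5055e-06,0.307661,0.000472274
H,100,3.36819e-06,0.293398,0.000309076
C,1,1814.46,0.00275033,14.4319
C,1.5,548.63,0.0158728,6.67962
C,2,234.806,0.0348691,3.86694
C,3,70.9971,0.0708404,1.78976
C,4,30.3859,0.0972226,1.03612
C,5,15.7321,0.11571,0.678081
C,6,9.18761,0.128876,0.479554
C,8,3.93218,0.14569,0.277622
C,10,2.03586,0.15545,0.181687
C,12,1.18895,0.161468,0.128493
C,15,0.615573,0.166691,0.0840914
C,20,0.263457,0.170388,0.0486819
C,25,0.136403,0.171216,0.0318595
C,30,0.0796601,0.170728,0.0225317
C,40,0.0340935,0.168046,0.013044
C,50,0.0176517,0.164503,0.00853654
C,60,0.0103087,0.160744,0.00603723
C,80,0.00441198,0.153394,0.00349505
C,100,0.00228428,0.146648,0.00228731
N,1,3117.52,0.00175193,18.1939
N,1.5,942.628,0.0121648,8.42078
N,2,403.433,0.0290403,4.87494
N,3,121.984,0.0636005,2.25629
N,4,52.2075,0.0902843,1.30621
N,5,27.0301,0.109486,0.854836
N,6,15.7857,0.123386,0.604559
N,8,6.75607,0.141409,0.349989
N,10,3.49792,0.152035,0.229048
N,12,2.0428,0.158677,0.161988
N,15,1.05765,0.164548,0.106011
N,20,0.452659,0.1689,0.0613718
N,25,0.234362,0.170114,0.0401643
N,30,0.136868,0.169875,0.028405
N,40,0.0585777,0.16749,0.0164442
N,50,0.0303283,0.164112,0.0107617
N,60,0.0177118,0.160457,0.00761094
N,80,0.00758043,0.153225,0.00440611
N,100,0.00392473,0.146543,0.00288354
O,1,4922.48,0.00114107,22.2412
O,1.5,1488.38,0.00944684,10.294
O,2,637.009,0.0244075,5.95938
O,3,192.609,0.0574123,2.75821
O,4,82.4342,0.0841596,1.59678
O,5,42.6798,0.103895,1.045
O,6,24.9252,0.118401,0.739045
O,8,10.6677,0.137478,0.427846
O,10,5.52312,0.148883,0.28
O,12,3.22552,0.156094,0.198022
O,15,1.66999,0.162562,0.129594
O,20,0.714736,0.167524,0.0750241
O,25,0.370051,0.169101,0.0490989
O,30,0.216111,0.169096,0.0347238
O,40,0.0924927,0.16699,0.0201022
O,50,0.0478876,0.163769,0.0131557
O,60,0.0279665,0.160212,0.00930402
O,80,0.0119693,0.153091,0.00538626
O,100,0.00619704,0.146467,0.00352499
Na,1,13131.5,0.000332962,34.3138
Na,1.5,3970.5,0.00448411,15.8816
Na,2,1699.32,0.0144182,9.19415
Na,3,513.815,0.0413247,4.25538
Na,4,219.906,0.0662048,2.46351
Na,5,113.855,0.0858621,1.61222
Na,6,66.4918,0.100924,1.1402
Na,8,28.4576,0.12149,0.660082
Na,10,14.7338,0.134231,0.431985
Na,12,8.60458,0.142511,0.305509
Na,15,4.45497,0.150182,0.199938
Na,20,1.90667,0.156472,0.115748
Na,25,0.987168,0.158909,0.07575
Na,30,0.57651,0.159512,0.053572
Na,40,0.246739,0.158228,0.0310138
Na,50,0.127748,0.15556,0.0202967
Na,60,0.074605,0.152417,0.0143543
Na,80,0.03193,0.145906,0.00830994
Na,100,0.0165316,0.139734,0.00543837
Mg,1,18187,0.00023742,40.3444
Mg,1.5,5499.1,0.00372012,18.6728
Mg,2,2353.54,0.0128043,10.81
Mg,3,711.628,0.0390266,5.00326
Mg,4,304.568,0.0642757,2.89647
Mg,5,157.688,0.0846497,1.89557
Mg,6,92.0904,0.100461,1.34059
Mg,8,39.4135,0.122298,0.776091
Mg,10,20.4061,0.135969,0.507906
Mg,12,11.9172,0.144921,0.359202
Mg,15,6.17009,0.153285,0.235077
Mg,20,2.64072,0.160251,0.13609
Mg,25,1.36722,0.163055,0.089063
Mg,30,0.798459,0.163869,0.0629873
Mg,40,0.34173,0.162775,0.0364644
Mg,50,0.176929,0.160154,0.0238638
Mg,60,0.103327,0.156994,0.016877
Mg,80,0.0442227,0.150372,0.0097704
Mg,100,0.022896,0.144055,0.00639416
Si,1,29510.5,0.000118046,51.33
Si,1.5,8922.92,0.00247244,23.7574
Si,2,3818.9,0.00969583,13.7535
Si,3,1154.7,0.0332489,6.36563
Si,4,494.196,0.0577397,3.68517
Si,5,255.867,0.0783122,2.41173
Si,6,149.427,0.0946702,1.70563
Si,8,63.953,0.117755,0.987417
Si,10,33.1113,0.132492,0.646207
Si,12,19.3371,0.142277,0.457012
Si,15,10.0117,0.151554,0.299087
Si,20,4.28487,0.15948,0.173147
Si,25,2.21847,0.162861,0.113315
Si,30,1.29559,0.164047,0.0801385
Si,40,0.554497,0.163386,0.0463935
Si,50,0.287088,0.160991,0.0303619
Si,60,0.16766,0.157961,0.0214726
Si,80,0.0717564,0.151461,0.0124308
Si,100,0.0371515,0.145186,0.00813526
P,1,35005.9,8.1564e-05,55.304
P,1.5,10584.5,0.00196428,25.5967
P,2,4530.04,0.00820203,14.8183
P,3,1369.72,0.0297671,6.85846
P,4,586.224,0.053028,3.97048
P,5,303.514,0.0729468,2.59845
P,6,177.253,0.0889702,1.83768
P,8,75.8622,0.111817,1.06386
P,10,39.2772,0.126535,0.696236
P,12,22.938,0.136372,0.492394
P,15,11.876,0.145757,0.322243
P,20,5.08279,0.153863,0.186552
P,25,2.63159,0.1574,0.122087
P,30,1.53686,0.15872,0.0863428
P,40,0.657755,0.158282,0.0499854
P,50,0.340549,0.156073,0.0327125
P,60,0.198882,0.153203,0.023135
P,80,0.0851188,0.146976,0.0133932
P,100,0.0440698,0.140927,0.0087651
S,1,44011.2,6.02537e-05,62.7859
S,1.5,13307.4,0.00166311,29.0596
S,2,5695.4,0.00738358,16.8231
S,3,1722.09,0.0283229,7.78631
S,4,737.031,0.0517274,4.50763
S,5,381.594,0.0721484,2.94998
S,6,222.852,0.0887626,2.08629
S,8,95.3778,0.11269,1.20779
S,10,49.3813,0.128241,0.790428
S,12,28.8389,0.138698,0.559008
S,15,14.9312,0.148735,0.365838
S,20,6.39034,0.157491,0.21179
S,25,3.30857,0.161386,0.138604
S,30,1.93221,0.162913,0.0980239
S,40,0.826962,0.162666,0.0567477
S,50,0.428155,0.160508,0.0371381
S,60,0.250044,0.157625,0.0262649
S,80,0.107016,0.151294,0.0152052
S,100,0.0554068,0.145108,0.0099509
Cl,1,50575.8,4.18036e-05,66.0742
Cl,1.5,15292.3,0.00131856,30.5815
Cl,2,6544.91,0.00621582,17.7041
Cl,3,1978.95,0.0251712,8.19411
Cl,4,846.965,0.047105,4.74371
Cl,5,438.511,0.0665959,3.10448
Cl,6,256.092,0.0826294,2.19556
Cl,8,109.604,0.105947,1.27105
Cl,10,56.7469,0.121231,0.831825
Cl,12,33.1404,0.131569,0.588285
Cl,15,17.1583,0.141548,0.384998
Cl,20,7.34352,0.150332,0.222882
Cl,25,3.80206,0.154307,0.145863
Cl,30,2.22042,0.155931,0.103158
Cl,40,0.95031,0.155885,0.0597198
Cl,50,0.492018,0.153921,0.0390831
Cl,60,0.28734,0.15122,0.0276404
Cl,80,0.122978,0.145219,0.0160015
Cl,100,0.0636711,0.13932,0.0104721
K,1,69504.2,2.25177e-05,79.1144
K,1.5,21015.6,0.000920135,36.6169
K,2,8994.41,0.00487306,21.1982
K,3,2719.59,0.0219216,9.81126
K,4,1163.95,0.0430096,5.67991
K,5,602.628,0.062423,3.71717
K,6,351.937,0.0787369,2.62886
K,8,150.624,0.102913,1.52189
K,10,77.985,0.119022,0.995991
K,12,45.5435,0.130037,0.704386
K,15,23.5799,0.140783,0.46098
K,20,10.0919,0.150394,0.266869
K,25,5.22502,0.154872,0.17465
K,30,3.05143,0.15682,0.123517
K,40,1.30597,0.157146,0.0715058
K,50,0.67616,0.15537,0.0467964
K,60,0.39488,0.15277,0.0330954
K,80,0.169003,0.146848,0.0191595
K,100,0.0875006,0.140958,0.0125388
Ca,1,82151.1,1.70074e-05,87.7394
Ca,1.5,24839.6,0.000788175,40.6089
Ca,2,10631,0.00441718,23.5092
Ca,3,3214.44,0.0209128,10.8809
Ca,4,1375.74,0.0419842,6.29913
Ca,5,712.282,0.0617171,4.12242
Ca,6,415.975,0.0784718,2.91546
Ca,8,178.032,0.103528,1.68781
Ca,10,92.1751,0.120355,1.10457
Ca,12,53.8305,0.131922,0.781179
Ca,15,27.8705,0.143261,0.511236
Ca,20,11.9282,0.153476,0.295963
Ca,25,6.17576,0.158295,0.193691
Ca,30,3.60666,0.160444,0.136982
Ca,40,1.54361,0.160962,0.0793014
Ca,50,0.799194,0.159245,0.0518981
Ca,60,0.466732,0.156643,0.0367035
Ca,80,0.199755,0.150642,0.0212483
Ca,100,0.103422,0.144637,0.0139058
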