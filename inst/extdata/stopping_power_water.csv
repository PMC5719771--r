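energy_MeV,value
0.01,22.560808
0.01079801,21.256438
0.011659703,20.026354
0.012590159,18.866762
0.013594867,17.774022
0.014679751,16.744649
0.01585121,15.775308
0.017116153,14.862814
0.01848204,14.004121
0.019956925,13.196329
0.021549509,12.43667
0.023269182,11.72251
0.025126086,11.051342
0.027131174,10.420783
0.02929627,9.8285674
0.031634142,9.2725453
0.034158579,8.7506762
0.036884469,8.2610254
0.039827888,7.8017593
0.043006194,7.3711411
0.046438133,6.9675269
0.050143943,6.5893613
0.054145482,6.2351738
0.058466347,5.9035743
0.063132022,5.59325
0.068170022,5.3029612
0.07361006,5.0315382
0.079484218,4.7778774
0.085827141,4.5409385
0.092676235,4.3197411
0.10007189,4.1133615
0.10805773,3.92093
0.11668085,3.7416281
0.1259921,3.5746854
0.1360464,3.4193774
0.14690305,3.2750228
0.15862606,3.1409811
0.17128459,3.0166503
0.18495327,2.9014646
0.19971273,2.7948925
0.21565002,2.6964343
0.23285911,2.6056206
0.25144151,2.5220101
0.2715068,2.445188
0.29317332,2.374764
0.31656885,2.3103707
0.34183137,2.2516622
0.36910987,2.1983124
0.39856521,2.1500138
0.43037113,2.1064757
0.46471519,2.0674234
0.50179994,2.0325966
0.54184409,1.9993284
0.58508381,1.9687527
0.6317741,1.9416315
0.68219032,1.9177409
0.73662981,1.8968669
0.79541363,1.878805
0.85888846,1.8633601
0.92742864,1.8503453
1.0014384,1.8395824
1.0813542,1.830901
1.1676474,1.8241387
1.2608269,1.8191407
1.3614421,1.8157596
1.4700866,1.8138557
1.5874011,1.8132965
1.7140773,1.8139568
1.8508624,1.8157187
1.9985632,1.8184713
2.1580505,1.8221107
2.3302652,1.8265402
2.5162228,1.8316695
2.7170199,1.837415
2.9338409,1.8436998
3.1679645,1.8504528
3.4207713,1.8576091
3.6937523,1.8651093
3.9885176,1.8728998
4.3068054,1.8809316
4.6504929,1.8891611
5.021607,1.8975487
5.4223364,1.9060596
5.8550445,1.9146623
6.3222831,1.9233295
6.8268078,1.932037
7.371594,1.9407634
7.9598548,1.9494906
8.5950595,1.9582027
9.280954,1.9668862
10.021584,1.9755296
10.821316,1.9841232
11.684869,1.9926592
12.617333,2.0011312
13.624209,2.0095338
14.711435,2.0178633
15.885423,2.0261165
17.153096,2.0342915
18.521931,2.042387
20,2.0504024
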