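energy_MeV,value
0.01,21.980298
0.01079801,20.708674
0.011659703,19.509542
0.012590159,18.379193
0.013594867,17.314068
0.014679751,16.310763
0.01585121,15.366018
0.017116153,14.47672
0.01848204,13.639896
0.019956925,12.852713
0.021549509,12.112467
0.023269182,11.416587
0.025126086,10.762625
0.027131174,10.148255
0.02929627,9.5712666
0.031634142,9.0295609
0.034158579,8.5211469
0.036884469,8.0441368
0.039827888,7.5967418
0.043006194,7.1772675
0.046438133,6.7841103
0.050143943,6.4157534
0.054145482,6.0707622
0.058466347,5.7477814
0.063132022,5.4455306
0.068170022,5.1628011
0.07361006,4.8984523
0.079484218,4.6514084
0.085827141,4.4206551
0.092676235,4.2052366
0.10007189,4.0042527
0.10805773,3.8168555
0.11668085,3.6422472
0.1259921,3.4796771
0.1360464,3.328439
0.14690305,3.1878689
0.15862606,3.0573427
0.17128459,2.9362737
0.18495327,2.8241108
0.19971273,2.7203357
0.21565002,2.624462
0.23285911,2.536032
0.25144151,2.454616
0.2715068,2.3798096
0.29317332,2.3112328
0.31656885,2.2485276
0.34183137,2.1913572
0.36910987,2.1394039
0.39856521,2.0923679
0.43037113,2.0489029
0.46471519,2.0077367
0.50179994,1.9706383
0.54184409,1.9373568
0.58508381,1.9076528
0.6317741,1.8812983
0.68219032,1.8580759
0.73662981,1.8377778
0.79541363,1.8202056
0.85888846,1.8051698
0.92742864,1.792489
1.0014384,1.7819903
1.0813542,1.7735084
1.1676474,1.7668855
1.2608269,1.7619715
1.3614421,1.7586234
1.4700866,1.7567057
1.5874011,1.7560898
1.7140773,1.7566544
1.8508624,1.7582849
1.9985632,1.760874
2.1580505,1.7643209
2.3302652,1.7685317
2.5162228,1.7734191
2.7170199,1.778902
2.9338409,1.7849057
3.1679645,1.7913615
3.4207713,1.7982065
3.6937523,1.8053833
3.9885176,1.8128397
4.3068054,1.8205286
4.6504929,1.8284075
5.021607,1.8364385
5.4223364,1.8445875
5.8550445,1.8528244
6.3222831,1.8611227
6.8268078,1.869459
7.371594,1.8778129
7.9598548,1.8861668
8.5950595,1.8945054
9.280954,1.9028157
10.021584,1.9110868
10.821316,1.9193095
11.684869,1.9274762
12.617333,1.9355809
13.624209,1.9436185
14.711435,1.9515856
15.885423,1.9594792
17.153096,1.9672977
18.521931,1.9750398
20,1.9827053
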