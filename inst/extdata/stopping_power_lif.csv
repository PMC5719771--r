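energy_MeV,value
0.01,17.959067
0.01079801,16.932534
0.011659703,15.963436
0.012590159,15.048941
0.013594867,14.186323
0.014679751,13.372962
0.01585121,12.606339
0.017116153,11.884043
0.01848204,11.203763
0.019956925,10.563288
0.021549509,9.9605066
0.023269182,9.3934009
0.025126086,8.8600477
0.027131174,8.3586139
0.02929627,7.8873542
0.031634142,7.4446081
0.034158579,7.0287968
0.036884469,6.6384206
0.039827888,6.2720559
0.043006194,5.928352
0.046438133,5.6060283
0.050143943,5.3038716
0.054145482,5.020733
0.058466347,4.7555251
0.063132022,4.5072197
0.068170022,4.2748444
0.07361006,4.057481
0.079484218,3.8542618
0.085827141,3.6643684
0.092676235,3.4870282
0.10007189,3.3215131
0.10805773,3.1671366
0.11668085,3.023252
0.1259921,2.8892501
0.1360464,2.7645577
0.14690305,2.6486351
0.15862606,2.5409747
0.17128459,2.4410988
0.18495327,2.3485584
0.19971273,2.2629311
0.21565002,2.1838199
0.23285911,2.1105055
0.25144151,2.042383
0.2715068,1.9795722
0.29317332,1.9217746
0.31656885,1.8687068
0.34183137,1.8200996
0.36910987,1.7756974
0.39856521,1.7352572
0.43037113,1.6985477
0.46471519,1.6653488
0.50179994,1.6354506
0.54184409,1.6086526
0.58508381,1.5847636
0.6317741,1.5636006
0.68219032,1.5449885
0.73662981,1.5287599
0.79541363,1.5147541
0.85888846,1.5028174
0.92742864,1.4928026
1.0014384,1.4845685
1.0813542,1.4779803
1.1676474,1.4729091
1.2608269,1.4692318
1.3614421,1.4668312
1.4700866,1.4655959
1.5874011,1.4654203
1.7140773,1.4662044
1.8508624,1.4678541
1.9985632,1.4702809
2.1580505,1.4734018
2.3302652,1.4771394
2.5162228,1.4814217
2.7170199,1.4861821
2.9338409,1.4913591
3.1679645,1.4968963
3.4207713,1.5027419
3.6937523,1.508849
3.9885176,1.5151749
4.3068054,1.5216812
4.6504929,1.5283332
5.021607,1.5351003
5.4223364,1.5419548
5.8550445,1.5488727
6.3222831,1.5558326
6.8268078,1.5628159
7.371594,1.5698065
7.9598548,1.5767907
8.5950595,1.5837565
9.280954,1.5906941
10.021584,1.597595
10.821316,1.6044526
11.684869,1.6112613
12.617333,1.6180169
13.624209,1.624716
14.711435,1.6313562
15.885423,1.6379361
17.153096,1.6444548
18.521931,1.6509119
20,1.6573079
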