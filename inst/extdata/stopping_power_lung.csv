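energy_MeV,value
0.01,22.355962
0.01079801,21.063684
0.011659703,19.844981
0.012590159,18.696097
0.013594867,17.613431
0.014679751,16.593532
0.01585121,15.633098
0.017116153,14.728974
0.01848204,13.878148
0.019956925,13.077743
0.021549509,12.325023
0.023269182,11.617376
0.025126086,10.952322
0.027131174,10.327498
0.02929627,9.7406632
0.031634142,9.1896867
0.034158579,8.6725479
0.036884469,8.1873304
0.039827888,7.7322179
0.043006194,7.3054903
0.046438133,6.905519
0.050143943,6.5307634
0.054145482,6.1797667
0.058466347,5.8511518
0.063132022,5.5436183
0.068170022,5.255938
0.07361006,4.9869519
0.079484218,4.735567
0.085827141,4.5007525
0.092676235,4.2815369
0.10007189,4.0770053
0.10805773,3.886296
0.11668085,3.7085977
0.1259921,3.5431475
0.1360464,3.3892273
0.14690305,3.2461621
0.15862606,3.1133173
0.17128459,2.9900963
0.18495327,2.8759386
0.19971273,2.7703174
0.21565002,2.6727377
0.23285911,2.5827344
0.25144151,2.49987
0.2715068,2.4237335
0.29317332,2.3539382
0.31656885,2.2901201
0.34183137,2.2319364
0.36910987,2.1790639
0.39856521,2.1311977
0.43037113,2.08805
0.46471519,2.0493484
0.50179994,2.0137962
0.54184409,1.9799767
0.58508381,1.9498007
0.6317741,1.9230367
0.68219032,1.8994636
0.73662981,1.8788704
0.79541363,1.8610552
0.85888846,1.8458251
0.92742864,1.8329958
1.0014384,1.8223911
1.0813542,1.8138426
1.1676474,1.8071897
1.2608269,1.8022793
1.3614421,1.7989658
1.4700866,1.797111
1.5874011,1.7965838
1.7140773,1.7972604
1.8508624,1.799024
1.9985632,1.8017651
2.1580505,1.8053809
2.3302652,1.8097756
2.5162228,1.8148599
2.7170199,1.8205513
2.9338409,1.8267735
3.1679645,1.8334564
3.4207713,1.8405357
3.6937523,1.8479528
3.9885176,1.8556546
4.3068054,1.863593
4.6504929,1.8717247
5.021607,1.8800107
5.4223364,1.8884167
5.8550445,1.8969117
6.3222831,1.9054687
6.8268078,1.914064
7.371594,1.9226766
7.9598548,1.9312887
8.5950595,1.9398847
9.280954,1.9484514
10.021584,1.9569775
10.821316,1.9654538
11.684869,1.9738726
12.617333,1.9822276
13.624209,1.9905138
14.711435,1.9987275
15.885423,2.0068659
17.153096,2.0149271
18.521931,2.02291
20,2.0308142
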