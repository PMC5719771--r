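energy_MeV,value
0.01,0.57665601
0.01079801,0.50144073
0.011659703,0.44152594
0.012590159,0.39375198
0.013594867,0.35560854
0.014679751,0.3251011
0.01585121,0.30064477
0.017116153,0.28098003
0.01848204,0.26510578
0.019956925,0.25222618
0.021549509,0.24170846
0.023269182,0.23304935
0.025126086,0.22584851
0.027131174,0.21978735
0.02929627,0.21461229
0.031634142,0.21012144
0.034158579,0.206154
0.036884469,0.20258196
0.039827888,0.19930335
0.043006194,0.19623709
0.046438133,0.19331873
0.050143943,0.19049718
0.054145482,0.18773213
0.058466347,0.18499191
0.063132022,0.18225194
0.068170022,0.17949337
0.07361006,0.17670206
0.079484218,0.1738678
0.085827141,0.17098361
0.092676235,0.16804525
0.10007189,0.16505074
0.10805773,0.16200002
0.11668085,0.15889468
0.1259921,0.15573762
0.1360464,0.15253289
0.14690305,0.14928541
0.15862606,0.14600082
0.17128459,0.1426853
0.18495327,0.13934535
0.19971273,0.13598768
0.21565002,0.13261906
0.23285911,0.12924618
0.25144151,0.12587552
0.2715068,0.12251328
0.29317332,0.11916529
0.31656885,0.11583695
0.34183137,0.11253316
0.36910987,0.10925838
0.39856521,0.1060165
0.43037113,0.10281098
0.46471519,0.099644783
0.50179994,0.09652045
0.54184409,0.093440138
0.58508381,0.090405669
0.6317741,0.087418577
0.68219032,0.084480168
0.73662981,0.081591561
0.79541363,0.078753737
0.85888846,0.075967577
0.92742864,0.073233895
1.0014384,0.070553462
1.0813542,0.067927026
1.1676474,0.065355321
1.2608269,0.062839075
1.3614421,0.060379007
1.4700866,0.057975825
1.5874011,0.055630213
1.7140773,0.053342826
1.8508624,0.051114272
1.9985632,0.048945104
2.1580505,0.046835799
2.3302652,0.044786756
2.5162228,0.042798275
2.7170199,0.040870551
2.9338409,0.039003669
3.1679645,0.037197591
3.4207713,0.035452159
3.6937523,0.034114903
3.9885176,0.032841437
4.3068054,0.031627394
4.6504929,0.030472126
5.021607,0.029374869
5.4223364,0.028334751
5.8550445,0.0273508
6.3222831,0.026421952
6.8268078,0.025547057
7.371594,0.024724891
7.9598548,0.023954163
8.5950595,0.023233527
9.280954,0.022561587
10.021584,0.02193691
10.821316,0.021358032
11.684869,0.020823465
12.617333,0.020331709
13.624209,0.019881255
14.711435,0.019470594
15.885423,0.019098224
17.153096,0.018762652
18.521931,0.018462402
20,0.01819602
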