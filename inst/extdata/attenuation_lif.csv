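energy_MeV,value
0.01,0.60921059
0.01079801,0.52006536
0.011659703,0.44911531
0.012590159,0.39260723
0.013594867,0.34755952
0.014679751,0.31160339
0.01585121,0.28285683
0.017116153,0.25982442
0.01848204,0.24131782
0.019956925,0.2263926
0.021549509,0.21429803
0.023269182,0.20443732
0.025126086,0.19633591
0.027131174,0.18961638
0.02929627,0.18397851
0.031634142,0.17918342
0.034158579,0.17504106
0.036884469,0.17140017
0.039827888,0.16814042
0.043006194,0.16516611
0.046438133,0.16240122
0.050143943,0.15978546
0.054145482,0.15727114
0.058466347,0.15482069
0.063132022,0.15240474
0.068170022,0.15000052
0.07361006,0.14759065
0.079484218,0.14516216
0.085827141,0.14270572
0.092676235,0.14021496
0.10007189,0.13768601
0.10805773,0.13511706
0.11668085,0.13250801
0.1259921,0.12986018
0.1360464,0.12717604
0.14690305,0.124459
0.15862606,0.12171319
0.17128459,0.11894332
0.18495327,0.11615445
0.19971273,0.1133519
0.21565002,0.11054108
0.23285911,0.10772739
0.25144151,0.1049161
0.2715068,0.10211225
0.29317332,0.099320629
0.31656885,0.096545646
0.34183137,0.093791353
0.36910987,0.091061394
0.39856521,0.088359004
0.43037113,0.08568702
0.46471519,0.083047895
0.50179994,0.080443729
0.54184409,0.077876306
0.58508381,0.075347131
0.6317741,0.072857478
0.68219032,0.070408424
0.73662981,0.068000899
0.79541363,0.065635715
0.85888846,0.063313602
0.92742864,0.061035237
1.0014384,0.05880126
1.0813542,0.056612292
1.1676474,0.054468944
1.2608269,0.052371821
1.3614421,0.050321522
1.4700866,0.048318635
1.5874011,0.046363732
1.7140773,0.044457356
1.8508624,0.042600015
1.9985632,0.040792167
2.1580505,0.039034214
2.3302652,0.037326484
2.5162228,0.035669229
2.7170199,0.034062611
2.9338409,0.0325067
3.1679645,0.031001466
3.4207713,0.029546775
3.6937523,0.028466593
3.9885176,0.027439952
4.3068054,0.026462837
4.6504929,0.025534706
5.021607,0.024654924
5.4223364,0.023822762
5.8550445,0.023037412
6.3222831,0.022297986
6.8268078,0.021603525
7.371594,0.020953011
7.9598548,0.020345367
8.5950595,0.01977947
9.280954,0.019254159
10.021584,0.018768237
10.821316,0.018320485
11.684869,0.017909663
12.617333,0.017534521
13.624209,0.017193802
14.711435,0.016886247
15.885423,0.016610605
17.153096,0.016365631
18.521931,0.016150095
20,0.015962785
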