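energy_MeV,value
0.01,0.59781483
0.01079801,0.51788649
0.011659703,0.4542297
0.012590159,0.4034851
0.013594867,0.36298382
0.014679751,0.33060536
0.01585121,0.30466481
0.017116153,0.28382317
0.01848204,0.26701627
0.019956925,0.25339814
0.021549509,0.24229621
0.023269182,0.23317561
0.025126086,0.2256109
0.027131174,0.21926357
0.02929627,0.2138642
0.031634142,0.20919834
0.034158579,0.20509523
0.036884469,0.2014189
0.039827888,0.19806114
0.043006194,0.19493583
0.046438133,0.19197457
0.050143943,0.18912313
0.054145482,0.18633868
0.058466347,0.18358757
0.063132022,0.18084362
0.068170022,0.17808671
0.07361006,0.17530171
0.079484218,0.17247757
0.085827141,0.16960668
0.092676235,0.16668424
0.10007189,0.16370785
0.10805773,0.16067711
0.11668085,0.15759329
0.1259921,0.15445906
0.1360464,0.15127823
0.14690305,0.14805556
0.15862606,0.14479654
0.17128459,0.14150717
0.18495327,0.13819385
0.19971273,0.13486319
0.21565002,0.13152184
0.23285911,0.1281764
0.25144151,0.12483327
0.2715068,0.12149858
0.29317332,0.11817808
0.31656885,0.11487713
0.34183137,0.11160058
0.36910987,0.10835281
0.39856521,0.10513772
0.43037113,0.10195869
0.46471519,0.098818686
0.50179994,0.09572021
0.54184409,0.092665402
0.58508381,0.089656063
0.6317741,0.086693717
0.68219032,0.083779655
0.73662981,0.080914986
0.79541363,0.078100683
0.85888846,0.075337618
0.92742864,0.072626598
1.0014384,0.069968387
1.0813542,0.067363727
1.1676474,0.064813345
1.2608269,0.062317963
1.3614421,0.059878294
1.4700866,0.057495039
1.5874011,0.055168878
1.7140773,0.052900458
1.8508624,0.050690385
1.9985632,0.048539205
2.1580505,0.046447392
2.3302652,0.044415341
2.5162228,0.04244335
2.7170199,0.040531613
2.9338409,0.038680212
3.1679645,0.036889112
3.4207713,0.035158154
3.6937523,0.033830355
3.9885176,0.032565798
4.3068054,0.031360173
4.6504929,0.030212834
5.021607,0.029123025
5.4223364,0.028089882
5.8550445,0.02711244
6.3222831,0.026189643
6.8268078,0.025320352
7.371594,0.024503353
7.9598548,0.023737366
8.5950595,0.023021055
9.280954,0.022353037
10.021584,0.021731889
10.821316,0.02115616
11.684869,0.020624375
12.617333,0.020135046
13.624209,0.019686676
14.711435,0.01927777
15.885423,0.018906837
17.153096,0.018572397
18.521931,0.018272986
20,0.018007161
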