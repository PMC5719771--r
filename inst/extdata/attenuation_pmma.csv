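energy_MeV,value
0.01,0.42789987
0.01079801,0.38205826
0.011659703,0.34547905
0.012590159,0.3162451
0.013594867,0.29283307
0.014679751,0.27403235
0.01585121,0.25888071
0.017116153,0.2466132
0.01848204,0.23662158
0.019956925,0.22842207
0.021549509,0.22162976
0.023269182,0.21593828
0.025126086,0.21110369
0.027131174,0.20693166
0.02929627,0.2032673
0.031634142,0.19998713
0.034158579,0.19699264
0.036884469,0.1942053
0.039827888,0.19156247
0.043006194,0.18901428
0.046438133,0.18652107
0.050143943,0.18405148
0.054145482,0.18158082
0.058466347,0.17908984
0.063132022,0.17656378
0.068170022,0.17399161
0.07361006,0.17136536
0.079484218,0.16867968
0.085827141,0.16593143
0.092676235,0.16311938
0.10007189,0.1602439
0.10805773,0.15730678
0.11668085,0.15431098
0.1259921,0.15126049
0.1360464,0.14816014
0.14690305,0.14501546
0.15862606,0.1418325
0.17128459,0.1386177
0.18495327,0.13537777
0.19971273,0.13211951
0.21565002,0.12884972
0.23285911,0.12557509
0.25144151,0.12230205
0.2715068,0.11903675
0.29317332,0.11578495
0.31656885,0.11255195
0.34183137,0.1093426
0.36910987,0.10616124
0.39856521,0.10301173
0.43037113,0.099897429
0.46471519,0.096821248
0.50179994,0.093785677
0.54184409,0.090792823
0.58508381,0.087844469
0.6317741,0.084942117
0.68219032,0.082087039
0.73662981,0.079280331
0.79541363,0.07652295
0.85888846,0.073815756
0.92742864,0.071159543
1.0014384,0.068555061
1.0813542,0.06600304
1.1676474,0.063504195
1.2608269,0.061059233
1.3614421,0.058668855
1.4700866,0.056333748
1.5874011,0.054054579
1.7140773,0.051831983
1.8508624,0.049666554
1.9985632,0.047558826
2.1580505,0.045509267
2.3302652,0.043518261
2.5162228,0.041586101
2.7170199,0.039712978
2.9338409,0.037898972
3.1679645,0.036144048
3.4207713,0.034448052
3.6937523,0.033115401
3.9885176,0.031844365
4.3068054,0.03063107
4.6504929,0.029474885
5.021607,0.028375067
5.4223364,0.027330771
5.8550445,0.026341051
6.3222831,0.025404872
6.8268078,0.024521118
7.371594,0.0236886
7.9598548,0.022906064
8.5950595,0.0221722
9.280954,0.021485654
10.021584,0.020845032
10.821316,0.020248911
11.684869,0.019695846
12.617333,0.01918438
13.624209,0.018713046
14.711435,0.018280379
15.885423,0.017884917
17.153096,0.017525211
18.521931,0.017199828
20,0.016907352
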