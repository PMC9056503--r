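# material: water
# density_g_cm3: 1
# provenance: synthetic reference table, Bethe theory (I = 75.0 eV, Z/A = 0.55509) with empirical shell correction calibrated to published PSTAR water anchors; generated by tools/make_sp_tables.R
# description: liquid water (H2O)
energy_MeV,mass_sp_MeV_cm2_per_g
0.25,617.02427
0.27146328,591.73957
0.29476926,566.56384
0.32007612,541.62047
0.34755566,517.00684
0.37739441,492.84475
0.4097949,469.23339
0.44497708,446.25115
0.48317976,423.95859
0.52466225,402.40095
0.56970615,381.61043
0.61861721,361.60815
0.67172744,342.40585
0.72939735,324.00741
0.7920184,306.41013
0.86001566,289.6059
0.93385071,273.58213
1.0140247,258.32237
1.1010819,243.79589
1.1956133,229.97713
1.2982604,216.8456
1.4097201,204.3794
1.530749,192.55562
1.6621686,181.35065
1.804871,170.74045
1.9598249,160.7008
2.128082,151.20701
2.3107845,142.23239
2.5091726,133.75103
2.7245929,125.7383
2.9585078,118.1707
3.2125049,111.02586
3.4883086,104.28242
3.7877908,97.920023
4.1129845,91.919221
4.4660971,86.261466
4.8495256,80.929057
5.2658726,75.905096
5.7179642,71.173461
6.2088694,66.71877
6.7419203,62.526351
7.3207353,58.582212
7.9492434,54.873014
8.6317109,51.386049
9.3727703,48.109206
10.177452,45.031012
11.051218,42.142106
12,39.432701
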