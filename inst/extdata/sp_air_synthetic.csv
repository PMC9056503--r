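# material: air
# density_g_cm3: 0.00120479
# provenance: synthetic reference table, Bethe theory (I = 85.7 eV, Z/A = 0.49919) with empirical shell correction calibrated to published PSTAR water anchors; generated by tools/make_sp_tables.R
# description: dry air, near sea level
energy_MeV,mass_sp_MeV_cm2_per_g
0.25,516.50911
0.27146328,496.80385
0.29476926,476.95676
0.32007612,457.09778
0.34755566,437.33195
0.37739441,417.78487
0.4097949,398.56055
0.44497708,379.74313
0.48317976,361.39964
0.52466225,343.58232
0.56970615,326.33079
0.61861721,309.67384
0.67172744,293.63108
0.72939735,278.21431
0.7920184,263.42877
0.86001566,249.27421
0.93385071,235.74582
1.0140247,222.83479
1.1010819,210.519
1.1956133,198.78052
1.2982604,187.60562
1.4097201,176.9789
1.530749,166.88373
1.6621686,157.30252
1.804871,148.21701
1.9598249,139.60854
2.128082,131.45773
2.3107845,123.74321
2.5091726,116.44412
2.7245929,109.54051
2.9585078,103.01332
3.2125049,96.844303
3.4883086,91.016002
3.7877908,85.511702
4.1129845,80.315399
4.4660971,75.411769
4.8495256,70.786144
5.2658726,66.42448
5.7179642,62.313341
6.2088694,58.439871
6.7419203,54.791776
7.3207353,51.357301
7.9492434,48.125215
8.6317109,45.084792
9.3727703,42.225789
10.177452,39.538484
11.051218,37.015008
12,34.647066
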