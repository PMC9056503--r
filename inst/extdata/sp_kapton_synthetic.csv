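# material: kapton
# density_g_cm3: 1.42
# provenance: synthetic reference table, Bethe theory (I = 79.6 eV, Z/A = 0.51264) with empirical shell correction calibrated to published PSTAR water anchors; generated by tools/make_sp_tables.R
# description: kapton polyimide film (C22H10N2O5)
energy_MeV,mass_sp_MeV_cm2_per_g
0.25,552.24669
0.27146328,530.28591
0.29476926,508.31584
0.32007612,486.45913
0.34755566,464.81372
0.37739441,443.49946
0.4097949,422.61473
0.44497708,402.23821
0.48317976,382.43156
0.52466225,363.24186
0.56970615,344.70375
0.61861721,326.84122
0.67172744,309.66925
0.72939735,293.19525
0.7920184,277.42023
0.86001566,262.33994
0.93385071,247.94572
1.0140247,234.22513
1.1010819,221.15232
1.1956133,208.706
1.2982604,196.8694
1.4097201,185.62426
1.530749,174.95125
1.6621686,164.83023
1.804871,155.24054
1.9598249,146.16124
2.128082,137.57083
2.3107845,129.44586
2.5091726,121.76352
2.7245929,114.50208
2.9585078,107.64077
3.2125049,101.15981
3.4883086,95.040266
3.7877908,89.264063
4.1129845,83.813928
4.4660971,78.673351
4.8495256,73.826557
5.2658726,69.25847
5.7179642,64.954688
6.2088694,60.901451
6.7419203,57.085622
7.3207353,53.494661
7.9492434,50.116599
8.6317109,46.940019
9.3727703,43.954036
10.177452,41.148327
11.051218,38.514497
12,36.043742
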