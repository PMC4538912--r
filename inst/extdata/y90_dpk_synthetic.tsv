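# yttrium-90 radial dose-point kernel, reference soft tissue 1.04 g/cc
# SYNTHETIC: generated by sirtvox::y90_dpk() (fixed-seed condensed-history
# random walk: allowed-shape beta spectrum, Katz-Penfold range-energy
# relation, Highland angular diffusion scaled 0.5 to reproduce the
# published X90 = 5.43 mm in water); not a measured or published tabulation.
# support_mm=11 rho_ref=1.04 dr_mm=0.05 total_MeV_per_decay=0.937000
radius_mm	phi_mev_per_g
0.025	2.649328841e+04
0.075	2.904561697e+03
0.125	1.040646650e+03
0.175	5.309467678e+02
0.225	3.219660931e+02
0.275	2.169231514e+02
0.325	1.563210913e+02
0.375	1.190781785e+02
0.425	9.492555933e+01
0.475	7.931036397e+01
0.525	6.966663091e+01
0.575	6.197917213e+01
0.625	4.169726065e+01
0.675	3.434476078e+01
0.725	2.979413917e+01
0.775	2.606811452e+01
0.825	2.300480098e+01
0.875	2.045978716e+01
0.925	1.828229707e+01
0.975	1.647634547e+01
1.025	1.491964103e+01
1.075	1.359855129e+01
1.125	1.240961055e+01
1.175	1.136423687e+01
1.225	1.047017152e+01
1.275	9.680655248e+00
1.325	8.956374534e+00
1.375	8.328824538e+00
1.425	7.736622172e+00
1.475	7.194061325e+00
1.525	6.690553208e+00
1.575	6.214819823e+00
1.625	5.777507671e+00
1.675	5.343019444e+00
1.725	4.965090405e+00
1.775	4.617044321e+00
1.825	4.341055507e+00
1.875	4.099224354e+00
1.925	3.866242013e+00
1.975	3.650065340e+00
2.025	3.443290582e+00
2.075	3.257448481e+00
2.125	3.091885386e+00
2.175	2.931758226e+00
2.225	2.783794163e+00
2.275	2.637354077e+00
2.325	2.507718439e+00
2.375	2.386970740e+00
2.425	2.264390730e+00
2.475	2.149349553e+00
2.525	2.040933241e+00
2.575	1.946204443e+00
2.625	1.853993009e+00
2.675	1.764508665e+00
2.725	1.683047823e+00
2.775	1.601780699e+00
2.825	1.530931515e+00
2.875	1.466523422e+00
2.925	1.404276737e+00
2.975	1.342908186e+00
3.025	1.285353021e+00
3.075	1.229069402e+00
3.125	1.180216991e+00
3.175	1.130026724e+00
3.225	1.079990087e+00
3.275	1.035290145e+00
3.325	9.957089677e-01
3.375	9.533838435e-01
3.425	9.105472646e-01
3.475	8.751566137e-01
3.525	8.387969360e-01
3.575	8.018456880e-01
3.625	7.695217383e-01
3.675	7.387385457e-01
3.725	7.091406836e-01
3.775	6.771476546e-01
3.825	6.522520775e-01
3.875	6.250377680e-01
3.925	6.006672617e-01
3.975	5.772028957e-01
4.025	5.507169283e-01
4.075	5.304842603e-01
4.125	5.087991344e-01
4.175	4.875390350e-01
4.225	4.695433805e-01
4.275	4.510356348e-01
4.325	4.324158497e-01
4.375	4.186759823e-01
4.425	4.004187885e-01
4.475	3.839529625e-01
4.525	3.661805083e-01
4.575	3.537045910e-01
4.625	3.392012636e-01
4.675	3.266938103e-01
4.725	3.118416619e-01
4.775	2.994640544e-01
4.825	2.868310775e-01
4.875	2.767945805e-01
4.925	2.632504606e-01
4.975	2.530862612e-01
5.025	2.434115885e-01
5.075	2.331747811e-01
5.125	2.239790486e-01
5.175	2.131656458e-01
5.225	2.047412290e-01
5.275	1.966856420e-01
5.325	1.881764565e-01
5.375	1.807177674e-01
5.425	1.728470164e-01
5.475	1.644771367e-01
5.525	1.587098056e-01
5.575	1.501924813e-01
5.625	1.436980820e-01
5.675	1.390184492e-01
5.725	1.315683784e-01
5.775	1.255783832e-01
5.825	1.198062481e-01
5.875	1.145894851e-01
5.925	1.085285345e-01
5.975	1.037818095e-01
6.025	9.894097037e-02
6.075	9.395038741e-02
6.125	8.892944208e-02
6.175	8.521490411e-02
6.225	8.120782002e-02
6.275	7.628181510e-02
6.325	7.205285129e-02
6.375	6.907381694e-02
6.425	6.475607736e-02
6.475	6.226503542e-02
6.525	5.829446350e-02
6.575	5.538941359e-02
6.625	5.240512412e-02
6.675	4.988703101e-02
6.725	4.709031422e-02
6.775	4.405979480e-02
6.825	4.169337515e-02
6.875	3.935281469e-02
6.925	3.692482492e-02
6.975	3.437461660e-02
7.025	3.258144687e-02
7.075	3.103792688e-02
7.125	2.907168260e-02
7.175	2.727122306e-02
7.225	2.522321040e-02
7.275	2.388793182e-02
7.325	2.182880975e-02
7.375	2.041965414e-02
7.425	1.915133794e-02
7.475	1.804538694e-02
7.525	1.690456938e-02
7.575	1.563363590e-02
7.625	1.452748490e-02
7.675	1.327732093e-02
7.725	1.221324509e-02
7.775	1.114562377e-02
7.825	1.028530821e-02
7.875	9.377281609e-03
7.925	8.556160533e-03
7.975	7.925770597e-03
8.025	7.134860856e-03
8.075	6.461583639e-03
8.125	6.022171160e-03
8.175	5.356744840e-03
8.225	4.931367819e-03
8.275	4.383090136e-03
8.325	3.894214658e-03
8.375	3.497358465e-03
8.425	3.158075075e-03
8.475	2.858346637e-03
8.525	2.530487848e-03
8.575	2.163589102e-03
8.625	1.997234521e-03
8.675	1.687194351e-03
8.725	1.458184904e-03
8.775	1.273466941e-03
8.825	1.034314665e-03
8.875	8.642397816e-04
8.925	7.835453008e-04
8.975	6.806843001e-04
9.025	5.541716549e-04
9.075	4.568913388e-04
9.125	3.483639670e-04
9.175	2.519256517e-04
9.225	2.217482128e-04
9.275	1.995215268e-04
9.325	1.473706010e-04
9.375	1.035104069e-04
9.425	8.121794615e-05
9.475	6.645834224e-05
9.525	4.445372512e-05
9.575	3.155008565e-05
9.625	2.561384907e-05
9.675	1.490344838e-05
9.725	2.747903708e-06
9.775	3.475259848e-06
9.825	3.240853852e-06
9.875	2.553651847e-06
9.925	0.000000000e+00
9.975	0.000000000e+00
10.025	0.000000000e+00
10.075	0.000000000e+00
10.125	0.000000000e+00
10.175	0.000000000e+00
10.225	0.000000000e+00
10.275	0.000000000e+00
10.325	0.000000000e+00
10.375	0.000000000e+00
10.425	0.000000000e+00
10.475	0.000000000e+00
10.525	0.000000000e+00
10.575	0.000000000e+00
10.625	0.000000000e+00
10.675	0.000000000e+00
10.725	0.000000000e+00
10.775	0.000000000e+00
10.825	0.000000000e+00
10.875	0.000000000e+00
10.925	0.000000000e+00
10.975	0.000000000e+00
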