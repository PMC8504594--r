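# Photon mass interaction coefficients for Cl (Z=17), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 2.828246e+03 8.555862e-03 3.033753e+00 2.831288e+03 2.828238e+03
1.044936e+00 2.519679e+03 9.231787e-03 3.011558e+00 2.522700e+03 2.519673e+03
1.091891e+00 2.244777e+03 9.959566e-03 2.989204e+00 2.247776e+03 2.244771e+03
1.140955e+00 1.999867e+03 1.074139e-02 2.966378e+00 2.002844e+03 1.999862e+03
1.192225e+00 1.781677e+03 1.157921e-02 2.942777e+00 1.784631e+03 1.781673e+03
1.245798e+00 1.587292e+03 1.247466e-02 2.918109e+00 1.590223e+03 1.587289e+03
1.301779e+00 1.414115e+03 1.342896e-02 2.892093e+00 1.417021e+03 1.414112e+03
1.360275e+00 1.259832e+03 1.444284e-02 2.864462e+00 1.262711e+03 1.259830e+03
1.421400e+00 1.122382e+03 1.551644e-02 2.834961e+00 1.125232e+03 1.122380e+03
1.485272e+00 9.999274e+02 1.664923e-02 2.803352e+00 1.002747e+03 9.999257e+02
1.552014e+00 8.889756e+02 1.784004e-02 2.769436e+00 8.917629e+02 8.889742e+02
1.621754e+00 7.898577e+02 1.908885e-02 2.733198e+00 7.926100e+02 7.898565e+02
1.694629e+00 7.017911e+02 2.039617e-02 2.694713e+00 7.045062e+02 7.017901e+02
1.770778e+00 6.235437e+02 2.176234e-02 2.654063e+00 6.262195e+02 6.235428e+02
1.850349e+00 5.540206e+02 2.318747e-02 2.611337e+00 5.566551e+02 5.540199e+02
1.933496e+00 4.922491e+02 2.467146e-02 2.566630e+00 4.948404e+02 4.922485e+02
2.020379e+00 4.371645e+02 2.621399e-02 2.520042e+00 4.397107e+02 4.371640e+02
2.111166e+00 3.876511e+02 2.781439e-02 2.471690e+00 3.901506e+02 3.876508e+02
2.206033e+00 3.437457e+02 2.947157e-02 2.421707e+00 3.461969e+02 3.437454e+02
2.305162e+00 3.048130e+02 3.118405e-02 2.370232e+00 3.072144e+02 3.048128e+02
2.408746e+00 2.702898e+02 3.295005e-02 2.317407e+00 2.726402e+02 2.702897e+02
2.516985e+00 2.396767e+02 3.476741e-02 2.263373e+00 2.419749e+02 2.396767e+02
2.630087e+00 2.125309e+02 3.663364e-02 2.208274e+00 2.147758e+02 2.125309e+02
2.748272e+00 1.884596e+02 3.854585e-02 2.152250e+00 1.906504e+02 1.884596e+02
2.821400e+00 1.753999e+02 3.970892e-02 2.118397e+00 1.775580e+02 1.753999e+02
2.823400e+00 1.633080e+03 3.974051e-02 2.117480e+00 1.635237e+03 1.499152e+03
2.871767e+00 1.587940e+03 4.050081e-02 2.095445e+00 1.590075e+03 1.459906e+03
3.000812e+00 1.469919e+03 4.249491e-02 2.037999e+00 1.472000e+03 1.356498e+03
3.135655e+00 1.342693e+03 4.452426e-02 1.980072e+00 1.344718e+03 1.243545e+03
3.276558e+00 1.211076e+03 4.658484e-02 1.921916e+00 1.213044e+03 1.125492e+03
3.423792e+00 1.081869e+03 4.867243e-02 1.863787e+00 1.083781e+03 1.008704e+03
3.577643e+00 9.600273e+02 5.078254e-02 1.805921e+00 9.618840e+02 8.978942e+02
3.738406e+00 8.487809e+02 5.291042e-02 1.748530e+00 8.505823e+02 7.962101e+02
3.906394e+00 7.499078e+02 5.505108e-02 1.691811e+00 7.516547e+02 7.054584e+02
4.081931e+00 6.640310e+02 5.719927e-02 1.635937e+00 6.657241e+02 6.263644e+02
4.265355e+00 5.899178e+02 5.935038e-02 1.581043e+00 5.915582e+02 5.578943e+02
4.457021e+00 5.252572e+02 6.150077e-02 1.527229e+00 5.268459e+02 4.979701e+02
4.657301e+00 4.682070e+02 6.364684e-02 1.474583e+00 4.697452e+02 4.449297e+02
4.866579e+00 4.173468e+02 6.578513e-02 1.423177e+00 4.188357e+02 3.974905e+02
5.085262e+00 3.715896e+02 6.791240e-02 1.373075e+00 3.730306e+02 3.546707e+02
5.313772e+00 3.303029e+02 7.002695e-02 1.324302e+00 3.316973e+02 3.159108e+02
5.552550e+00 2.932056e+02 7.212917e-02 1.276848e+00 2.945545e+02 2.809794e+02
5.802057e+00 2.600137e+02 7.422028e-02 1.230695e+00 2.613186e+02 2.496380e+02
6.062777e+00 2.304294e+02 7.630206e-02 1.185829e+00 2.316916e+02 2.216299e+02
6.335212e+00 2.041275e+02 7.837640e-02 1.142200e+00 2.053480e+02 1.966677e+02
6.619889e+00 1.807538e+02 8.044502e-02 1.099704e+00 1.819340e+02 1.744325e+02
6.917358e+00 1.599877e+02 8.250986e-02 1.058242e+00 1.611284e+02 1.546334e+02
7.228194e+00 1.415431e+02 8.457334e-02 1.017728e+00 1.426454e+02 1.370101e+02
7.552997e+00 1.251654e+02 8.663836e-02 9.780874e-01 1.262301e+02 1.213295e+02
7.892396e+00 1.106277e+02 8.870826e-02 9.392592e-01 1.116556e+02 1.073834e+02
8.247046e+00 9.772749e+01 9.078674e-02 9.011873e-01 9.871946e+01 9.498507e+01
8.617633e+00 8.628699e+01 9.287458e-02 8.637990e-01 8.724366e+01 8.397006e+01
9.004872e+00 7.614778e+01 9.497086e-02 8.270190e-01 7.706977e+01 7.419137e+01
9.409512e+00 6.716759e+01 9.707466e-02 7.907883e-01 6.805545e+01 6.551647e+01
9.832334e+00 5.921886e+01 9.918510e-02 7.550640e-01 6.007311e+01 5.782612e+01
1.027416e+01 5.218745e+01 1.013011e-01 7.198243e-01 5.300858e+01 5.101327e+01
1.073583e+01 4.597083e+01 1.034195e-01 6.851318e-01 4.675938e+01 4.498142e+01
1.121825e+01 4.047727e+01 1.055358e-01 6.510972e-01 4.123390e+01 3.964402e+01
1.172235e+01 3.562508e+01 1.076448e-01 6.178201e-01 3.635054e+01 3.492374e+01
1.224911e+01 3.134146e+01 1.097412e-01 5.853870e-01 3.203658e+01 3.075150e+01
1.279953e+01 2.756159e+01 1.118193e-01 5.538717e-01 2.822728e+01 2.706565e+01
1.337468e+01 2.422781e+01 1.138733e-01 5.233362e-01 2.486502e+01 2.381119e+01
1.397568e+01 2.128883e+01 1.158971e-01 4.938308e-01 2.189856e+01 2.093912e+01
1.460369e+01 1.869909e+01 1.178841e-01 4.653949e-01 1.928237e+01 1.840578e+01
1.525992e+01 1.641809e+01 1.198280e-01 4.380580e-01 1.697597e+01 1.617233e+01
1.594563e+01 1.440991e+01 1.217225e-01 4.118521e-01 1.494349e+01 1.420422e+01
1.666216e+01 1.264272e+01 1.235624e-01 3.868129e-01 1.315310e+01 1.247079e+01
1.741088e+01 1.108828e+01 1.253425e-01 3.629625e-01 1.157658e+01 1.094479e+01
1.819325e+01 9.721540e+00 1.270575e-01 3.403100e-01 1.018891e+01 9.602009e+00
1.901078e+01 8.520343e+00 1.287020e-01 3.188534e-01 8.967898e+00 8.420994e+00
1.986504e+01 7.465065e+00 1.302708e-01 2.985808e-01 7.893917e+00 7.382720e+00
2.075769e+01 6.538430e+00 1.317591e-01 2.794712e-01 6.949661e+00 6.470411e+00
2.169045e+01 5.724976e+00 1.331654e-01 2.614774e-01 6.119619e+00 5.669034e+00
2.266512e+01 5.011110e+00 1.344898e-01 2.445466e-01 5.390147e+00 4.965355e+00
2.368360e+01 4.384855e+00 1.357327e-01 2.286279e-01 4.749216e+00 4.347698e+00
2.474783e+01 3.835644e+00 1.368945e-01 2.136711e-01 4.186210e+00 3.805752e+00
2.585989e+01 3.354161e+00 1.379761e-01 1.996277e-01 3.691765e+00 3.330416e+00
2.702193e+01 2.932197e+00 1.389787e-01 1.864505e-01 3.257626e+00 2.913659e+00
2.823617e+01 2.562516e+00 1.399034e-01 1.740937e-01 2.876513e+00 2.548401e+00
2.950498e+01 2.238748e+00 1.407519e-01 1.625132e-01 2.542013e+00 2.228396e+00
3.083081e+01 1.955220e+00 1.415259e-01 1.516636e-01 2.248409e+00 1.948081e+00
3.221621e+01 1.707058e+00 1.422265e-01 1.415002e-01 1.990785e+00 1.702672e+00
3.366387e+01 1.489980e+00 1.428546e-01 1.319781e-01 1.764813e+00 1.487961e+00
3.517658e+01 1.300170e+00 1.434111e-01 1.230547e-01 1.566636e+00 1.300196e+00
3.675726e+01 1.134267e+00 1.438971e-01 1.146905e-01 1.392854e+00 1.136070e+00
3.840897e+01 9.893129e-01 1.443139e-01 1.068491e-01 1.240476e+00 9.926702e-01
4.013491e+01 8.627127e-01 1.446628e-01 9.949760e-02 1.106873e+00 8.674387e-01
4.193839e+01 7.522205e-01 1.449445e-01 9.260816e-02 9.897731e-01 7.581609e-01
4.382292e+01 6.557492e-01 1.451585e-01 8.615009e-02 8.870578e-01 6.627766e-01
4.579214e+01 5.715301e-01 1.453039e-01 8.009823e-02 7.969322e-01 5.795388e-01
4.784984e+01 4.980170e-01 1.453797e-01 7.442891e-02 7.178256e-01 5.069198e-01
5.000000e+01 4.338585e-01 1.453850e-01 6.911985e-02 6.483634e-01 4.435830e-01
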