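# Photon mass interaction coefficients for C (Z=6), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 2.209634e+03 1.262977e-02 1.078982e+00 2.210726e+03 2.208139e+03
1.044936e+00 1.952495e+03 1.363159e-02 1.067474e+00 1.953576e+03 1.951230e+03
1.091891e+00 1.725156e+03 1.471078e-02 1.055931e+00 1.726227e+03 1.724087e+03
1.140955e+00 1.524074e+03 1.587091e-02 1.044201e+00 1.525134e+03 1.523170e+03
1.192225e+00 1.346147e+03 1.711524e-02 1.032137e+00 1.347196e+03 1.345383e+03
1.245798e+00 1.188659e+03 1.844667e-02 1.019603e+00 1.189697e+03 1.188013e+03
1.301779e+00 1.049228e+03 1.986756e-02 1.006468e+00 1.050254e+03 1.048682e+03
1.360275e+00 9.257626e+02 2.137970e-02 9.926106e-01 9.267766e+02 9.253021e+02
1.421400e+00 8.164254e+02 2.298409e-02 9.779196e-01 8.174263e+02 8.160367e+02
1.485272e+00 7.195979e+02 2.468084e-02 9.622938e-01 7.205849e+02 7.192701e+02
1.552014e+00 6.338603e+02 2.646929e-02 9.456536e-01 6.348324e+02 6.335840e+02
1.621754e+00 5.579970e+02 2.835004e-02 9.280089e-01 5.589534e+02 5.577643e+02
1.694629e+00 4.909354e+02 3.032430e-02 9.094129e-01 4.918751e+02 4.907394e+02
1.770778e+00 4.317085e+02 3.239293e-02 8.899229e-01 4.326308e+02 4.315436e+02
1.850349e+00 3.794462e+02 3.455643e-02 8.695996e-01 3.803504e+02 3.793076e+02
1.933496e+00 3.333673e+02 3.681488e-02 8.485066e-01 3.342526e+02 3.332507e+02
2.020379e+00 2.927714e+02 3.916790e-02 8.267108e-01 2.936373e+02 2.926735e+02
2.111166e+00 2.570287e+02 4.161434e-02 8.042868e-01 2.578746e+02 2.569464e+02
2.206033e+00 2.255708e+02 4.415193e-02 7.813208e-01 2.263963e+02 2.255018e+02
2.305162e+00 1.978942e+02 4.677753e-02 7.579004e-01 1.986989e+02 1.978363e+02
2.408746e+00 1.735532e+02 4.948716e-02 7.341122e-01 1.743368e+02 1.735047e+02
2.516985e+00 1.521536e+02 5.227603e-02 7.100409e-01 1.529159e+02 1.521129e+02
2.630087e+00 1.333466e+02 5.513841e-02 6.857695e-01 1.340875e+02 1.333125e+02
2.748272e+00 1.168241e+02 5.806769e-02 6.613783e-01 1.175435e+02 1.167956e+02
2.871767e+00 1.023138e+02 6.105628e-02 6.369450e-01 1.030118e+02 1.022900e+02
3.000812e+00 8.957514e+01 6.409566e-02 6.125439e-01 9.025178e+01 8.955531e+01
3.135655e+00 7.839570e+01 6.717648e-02 5.882543e-01 7.905113e+01 7.837918e+01
3.276558e+00 6.858829e+01 7.028848e-02 5.641831e-01 6.922276e+01 6.857457e+01
3.423792e+00 5.998760e+01 7.342066e-02 5.404336e-01 6.060146e+01 5.997623e+01
3.577643e+00 5.244785e+01 7.656116e-02 5.170973e-01 5.304151e+01 5.243846e+01
3.738406e+00 4.584050e+01 7.969732e-02 4.942538e-01 4.641445e+01 4.583277e+01
3.906394e+00 4.005227e+01 8.281573e-02 4.719718e-01 4.060706e+01 4.004596e+01
4.081931e+00 3.498338e+01 8.590239e-02 4.503089e-01 3.551959e+01 3.497825e+01
4.265355e+00 3.054599e+01 8.894596e-02 4.293130e-01 3.106425e+01 3.054187e+01
4.457021e+00 2.666285e+01 9.193865e-02 4.090233e-01 2.716381e+01 2.665959e+01
4.657301e+00 2.326594e+01 9.487339e-02 3.894697e-01 2.375028e+01 2.326340e+01
4.866579e+00 2.029541e+01 9.774363e-02 3.706741e-01 2.076383e+01 2.029350e+01
5.085262e+00 1.769865e+01 1.005434e-01 3.526506e-01 1.815185e+01 1.769728e+01
5.313772e+00 1.542941e+01 1.032688e-01 3.354047e-01 1.586808e+01 1.542849e+01
5.552550e+00 1.344702e+01 1.059184e-01 3.189335e-01 1.387188e+01 1.344651e+01
5.802057e+00 1.171581e+01 1.084919e-01 3.032295e-01 1.212753e+01 1.171565e+01
6.062777e+00 1.020445e+01 1.109901e-01 2.882818e-01 1.060372e+01 1.020460e+01
6.335212e+00 8.885473e+00 1.134144e-01 2.740704e-01 9.272958e+00 8.885892e+00
6.619889e+00 7.734705e+00 1.157678e-01 2.605618e-01 8.111035e+00 7.735373e+00
6.917358e+00 6.731006e+00 1.180536e-01 2.477227e-01 7.096783e+00 6.731900e+00
7.228194e+00 5.855849e+00 1.202762e-01 2.355212e-01 6.211646e+00 5.856951e+00
7.552997e+00 5.093004e+00 1.224409e-01 2.239269e-01 5.439372e+00 5.094300e+00
7.892396e+00 4.428259e+00 1.245537e-01 2.129107e-01 4.765723e+00 4.429740e+00
8.247046e+00 3.849161e+00 1.266212e-01 2.024435e-01 4.178226e+00 3.850819e+00
8.617633e+00 3.344870e+00 1.286471e-01 1.924865e-01 3.666004e+00 3.346700e+00
9.004872e+00 2.905899e+00 1.306332e-01 1.829977e-01 3.219530e+00 2.907897e+00
9.409512e+00 2.523930e+00 1.325818e-01 1.739400e-01 2.830451e+00 2.526095e+00
9.832334e+00 2.191678e+00 1.344955e-01 1.652801e-01 2.491453e+00 2.194010e+00
1.027416e+01 1.902773e+00 1.363771e-01 1.569885e-01 2.196138e+00 1.905274e+00
1.073583e+01 1.651618e+00 1.382264e-01 1.490397e-01 1.938884e+00 1.654290e+00
1.121825e+01 1.433319e+00 1.400413e-01 1.414118e-01 1.714772e+00 1.436165e+00
1.172235e+01 1.243611e+00 1.418197e-01 1.340852e-01 1.519516e+00 1.246636e+00
1.224911e+01 1.078781e+00 1.435594e-01 1.270427e-01 1.349383e+00 1.081990e+00
1.279953e+01 9.355937e-01 1.452583e-01 1.202692e-01 1.201121e+00 9.389932e-01
1.337468e+01 8.112321e-01 1.469142e-01 1.137514e-01 1.071898e+00 8.148276e-01
1.397568e+01 7.032425e-01 1.485250e-01 1.074780e-01 9.592454e-01 7.070408e-01
1.460369e+01 6.094885e-01 1.500887e-01 1.014388e-01 8.610160e-01 6.134968e-01
1.525992e+01 5.281102e-01 1.516031e-01 9.562549e-02 7.753388e-01 5.323359e-01
1.594563e+01 4.574924e-01 1.530646e-01 9.003470e-02 7.005917e-01 4.619436e-01
1.666216e+01 3.962331e-01 1.544677e-01 8.466828e-02 6.353690e-01 4.009179e-01
1.741088e+01 3.431091e-01 1.558064e-01 7.952719e-02 5.784426e-01 3.480357e-01
1.819325e+01 2.970539e-01 1.570748e-01 7.461123e-02 5.287399e-01 3.022307e-01
1.901078e+01 2.571383e-01 1.582669e-01 6.991912e-02 4.853243e-01 2.625737e-01
1.986504e+01 2.225532e-01 1.593768e-01 6.544861e-02 4.473786e-01 2.282555e-01
2.075769e+01 1.925968e-01 1.603991e-01 6.119725e-02 4.141931e-01 1.985742e-01
2.169045e+01 1.666513e-01 1.613320e-01 5.716227e-02 3.851456e-01 1.729122e-01
2.266512e+01 1.441823e-01 1.621751e-01 5.334069e-02 3.596981e-01 1.507350e-01
2.368360e+01 1.247264e-01 1.629286e-01 4.972847e-02 3.373835e-01 1.315793e-01
2.474783e+01 1.078818e-01 1.635926e-01 4.632067e-02 3.177950e-01 1.150431e-01
2.585989e+01 9.329981e-02 1.641673e-01 4.311155e-02 3.005787e-01 1.007779e-01
2.702193e+01 8.067823e-02 1.646534e-01 4.009475e-02 2.854264e-01 8.848138e-02
2.823617e+01 6.975491e-02 1.650514e-01 3.726336e-02 2.720697e-01 7.789128e-02
2.950498e+01 6.030257e-02 1.653623e-01 3.461014e-02 2.602750e-01 6.878024e-02
3.083081e+01 5.212235e-02 1.655868e-01 3.212685e-02 2.498360e-01 6.094927e-02
3.221621e+01 4.504516e-02 1.657266e-01 2.980532e-02 2.405771e-01 5.422918e-02
3.366387e+01 3.892450e-02 1.657839e-01 2.763701e-02 2.323454e-01 4.847334e-02
3.517658e+01 3.363208e-02 1.657609e-01 2.561332e-02 2.250063e-01 4.355334e-02
3.675726e+01 2.905663e-02 1.656600e-01 2.372596e-02 2.184426e-01 3.935777e-02
3.840897e+01 2.510167e-02 1.654835e-01 2.196701e-02 2.125522e-01 3.578999e-02
4.013491e+01 2.168370e-02 1.652341e-01 2.032892e-02 2.072467e-01 3.276633e-02
4.193839e+01 1.873143e-02 1.649143e-01 1.880507e-02 2.024508e-01 3.021531e-02
4.382292e+01 1.618016e-02 1.645250e-01 1.738759e-02 1.980927e-01 2.807190e-02
4.579214e+01 1.397555e-02 1.640671e-01 1.606982e-02 1.941125e-01 2.628139e-02
4.784984e+01 1.207057e-02 1.635419e-01 1.484545e-02 1.904580e-01 2.479639e-02
5.000000e+01 1.042459e-02 1.629506e-01 1.370848e-02 1.870837e-01 2.357584e-02
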