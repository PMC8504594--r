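# Photon mass interaction coefficients for N (Z=7), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 3.310193e+03 1.100651e-02 1.291131e+00 3.311495e+03 3.310193e+03
1.044936e+00 2.935169e+03 1.190651e-02 1.280353e+00 2.936461e+03 2.935169e+03
1.091891e+00 2.602436e+03 1.287843e-02 1.269503e+00 2.603718e+03 2.602436e+03
1.140955e+00 2.307076e+03 1.392608e-02 1.258423e+00 2.308349e+03 2.307076e+03
1.192225e+00 2.044780e+03 1.505310e-02 1.246961e+00 2.046042e+03 2.044780e+03
1.245798e+00 1.811763e+03 1.626291e-02 1.234973e+00 1.813015e+03 1.811763e+03
1.301779e+00 1.604701e+03 1.755856e-02 1.222318e+00 1.605941e+03 1.604701e+03
1.360275e+00 1.420666e+03 1.894271e-02 1.208867e+00 1.421894e+03 1.420666e+03
1.421400e+00 1.257080e+03 2.041745e-02 1.194494e+00 1.258295e+03 1.257080e+03
1.485272e+00 1.111666e+03 2.198421e-02 1.179086e+00 1.112867e+03 1.111666e+03
1.552014e+00 9.824222e+02 2.364377e-02 1.162548e+00 9.836084e+02 9.824222e+02
1.621754e+00 8.676332e+02 2.539769e-02 1.144864e+00 8.688035e+02 8.676333e+02
1.694629e+00 7.657817e+02 2.724780e-02 1.126056e+00 7.669350e+02 7.657818e+02
1.770778e+00 6.754941e+02 2.919551e-02 1.106153e+00 6.766295e+02 6.754942e+02
1.850349e+00 5.955289e+02 3.124182e-02 1.085191e+00 5.966453e+02 5.955290e+02
1.933496e+00 5.247661e+02 3.338720e-02 1.063208e+00 5.258627e+02 5.247662e+02
2.020379e+00 4.621972e+02 3.563158e-02 1.040251e+00 4.632730e+02 4.621973e+02
2.111166e+00 4.069114e+02 3.797417e-02 1.016370e+00 4.079658e+02 4.069116e+02
2.206033e+00 3.580850e+02 4.041331e-02 9.916251e-01 3.591170e+02 3.580852e+02
2.305162e+00 3.149834e+02 4.294651e-02 9.660782e-01 3.159925e+02 3.149836e+02
2.408746e+00 2.769531e+02 4.557042e-02 9.397968e-01 2.779385e+02 2.769533e+02
2.516985e+00 2.434128e+02 4.828077e-02 9.128517e-01 2.443739e+02 2.434130e+02
2.630087e+00 2.138459e+02 5.107233e-02 8.853170e-01 2.147823e+02 2.138461e+02
2.748272e+00 1.877934e+02 5.393889e-02 8.572695e-01 1.887046e+02 1.877937e+02
2.871767e+00 1.648479e+02 5.687318e-02 8.287882e-01 1.657335e+02 1.648482e+02
3.000812e+00 1.446477e+02 5.986686e-02 7.999540e-01 1.455075e+02 1.446481e+02
3.135655e+00 1.268722e+02 6.291087e-02 7.708603e-01 1.277059e+02 1.268725e+02
3.276558e+00 1.112381e+02 6.599592e-02 7.416419e-01 1.120458e+02 1.112386e+02
3.423792e+00 9.749437e+01 6.911224e-02 7.124357e-01 9.827592e+01 9.749483e+01
3.577643e+00 8.541803e+01 7.224929e-02 6.833679e-01 8.617364e+01 8.541853e+01
3.738406e+00 7.481168e+01 7.539580e-02 6.545546e-01 7.554163e+01 7.481222e+01
3.906394e+00 6.550055e+01 7.853984e-02 6.261007e-01 6.620519e+01 6.550114e+01
4.081931e+00 5.732997e+01 8.166892e-02 5.981009e-01 5.800974e+01 5.733061e+01
4.265355e+00 5.016283e+01 8.477248e-02 5.706482e-01 5.081825e+01 5.016352e+01
4.457021e+00 4.387778e+01 8.784278e-02 5.438329e-01 4.450945e+01 4.387853e+01
4.657301e+00 3.836789e+01 9.087251e-02 5.177321e-01 3.897650e+01 3.836871e+01
4.866579e+00 3.353904e+01 9.385483e-02 4.924101e-01 3.412530e+01 3.353991e+01
5.085262e+00 2.930834e+01 9.678333e-02 4.679191e-01 2.987305e+01 2.930929e+01
5.313772e+00 2.560293e+01 9.965218e-02 4.443010e-01 2.614688e+01 2.560394e+01
5.552550e+00 2.235864e+01 1.024563e-01 4.215884e-01 2.288269e+01 2.235973e+01
5.802057e+00 1.951909e+01 1.051910e-01 3.998040e-01 2.002408e+01 1.952025e+01
6.062777e+00 1.703462e+01 1.078525e-01 3.789617e-01 1.752144e+01 1.703587e+01
6.335212e+00 1.486166e+01 1.104379e-01 3.590631e-01 1.533116e+01 1.486299e+01
6.619889e+00 1.296187e+01 1.129460e-01 3.400951e-01 1.341491e+01 1.296329e+01
6.917358e+00 1.130157e+01 1.153767e-01 3.220403e-01 1.173898e+01 1.130308e+01
7.228194e+00 9.851118e+00 1.177305e-01 3.048783e-01 1.027373e+01 9.852733e+00
7.552997e+00 8.584470e+00 1.200087e-01 2.885860e-01 8.993065e+00 8.586188e+00
7.892396e+00 7.478728e+00 1.222134e-01 2.731383e-01 7.874079e+00 7.480553e+00
8.247046e+00 6.513750e+00 1.243475e-01 2.585071e-01 6.896605e+00 6.515689e+00
8.617633e+00 5.671832e+00 1.264147e-01 2.446553e-01 6.042902e+00 5.673888e+00
9.004872e+00 4.937425e+00 1.284196e-01 2.315414e-01 5.297386e+00 4.939604e+00
9.409512e+00 4.296924e+00 1.303676e-01 2.191263e-01 4.646418e+00 4.299231e+00
9.832334e+00 3.738436e+00 1.322646e-01 2.073728e-01 4.078074e+00 3.740878e+00
1.027416e+01 3.251578e+00 1.341171e-01 1.962451e-01 3.581940e+00 3.254160e+00
1.073583e+01 2.827291e+00 1.359274e-01 1.857007e-01 3.148919e+00 2.830020e+00
1.121825e+01 2.457667e+00 1.376951e-01 1.756948e-01 2.771056e+00 2.460550e+00
1.172235e+01 2.135780e+00 1.394197e-01 1.661873e-01 2.441387e+00 2.138825e+00
1.224911e+01 1.855563e+00 1.411011e-01 1.571422e-01 2.153806e+00 1.858776e+00
1.279953e+01 1.611705e+00 1.427389e-01 1.485275e-01 1.902971e+00 1.615094e+00
1.337468e+01 1.399557e+00 1.443333e-01 1.403145e-01 1.684205e+00 1.403130e+00
1.397568e+01 1.215054e+00 1.458842e-01 1.324777e-01 1.493416e+00 1.218819e+00
1.460369e+01 1.054644e+00 1.473918e-01 1.249944e-01 1.327030e+00 1.058608e+00
1.525992e+01 9.152189e-01 1.488565e-01 1.178442e-01 1.181920e+00 9.193911e-01
1.594563e+01 7.940653e-01 1.502764e-01 1.110112e-01 1.055353e+00 7.984545e-01
1.666216e+01 6.888124e-01 1.516474e-01 1.044834e-01 9.449432e-01 6.934274e-01
1.741088e+01 5.973926e-01 1.529648e-01 9.824960e-02 8.486069e-01 6.022424e-01
1.819325e+01 5.180045e-01 1.542239e-01 9.229943e-02 7.645278e-01 5.230982e-01
1.901078e+01 4.490790e-01 1.554200e-01 8.662303e-02 6.911220e-01 4.544256e-01
1.986504e+01 3.892495e-01 1.565484e-01 8.121110e-02 6.270091e-01 3.948581e-01
2.075769e+01 3.373315e-01 1.576047e-01 7.605595e-02 5.709921e-01 3.432110e-01
2.169045e+01 2.922844e-01 1.585862e-01 7.115316e-02 5.220238e-01 2.984439e-01
2.266512e+01 2.532068e-01 1.594915e-01 6.649932e-02 4.791976e-01 2.596553e-01
2.368360e+01 2.193149e-01 1.603190e-01 6.208998e-02 4.417239e-01 2.260615e-01
2.474783e+01 1.899268e-01 1.610672e-01 5.791974e-02 4.089137e-01 1.969805e-01
2.585989e+01 1.644493e-01 1.617348e-01 5.398234e-02 3.801664e-01 1.718190e-01
2.702193e+01 1.423663e-01 1.623205e-01 5.027085e-02 3.549577e-01 1.500609e-01
2.823617e+01 1.232294e-01 1.628234e-01 4.677777e-02 3.328306e-01 1.312575e-01
2.950498e+01 1.066486e-01 1.632425e-01 4.349515e-02 3.133862e-01 1.150190e-01
3.083081e+01 9.228191e-02 1.635770e-01 4.041395e-02 2.962729e-01 1.010028e-01
3.221621e+01 7.983777e-02 1.638270e-01 3.752595e-02 2.811907e-01 8.891745e-02
3.366387e+01 6.906300e-02 1.639930e-01 3.482276e-02 2.678788e-01 7.850946e-02
3.517658e+01 5.973555e-02 1.640761e-01 3.229550e-02 2.561071e-01 6.955660e-02
3.675726e+01 5.166253e-02 1.640770e-01 2.993535e-02 2.456749e-01 6.186577e-02
3.840897e+01 4.467649e-02 1.639969e-01 2.773362e-02 2.364070e-01 5.526923e-02
4.013491e+01 3.863231e-02 1.638371e-01 2.568184e-02 2.281512e-01 4.962161e-02
4.193839e+01 3.340589e-02 1.635990e-01 2.377238e-02 2.207773e-01 4.479849e-02
4.382292e+01 2.888428e-02 1.632853e-01 2.199548e-02 2.141650e-01 4.068667e-02
4.579214e+01 2.497252e-02 1.628985e-01 2.034282e-02 2.082139e-01 3.719093e-02
4.784984e+01 2.158846e-02 1.624417e-01 1.880655e-02 2.028367e-01 3.422883e-02
5.000000e+01 1.866103e-02 1.619175e-01 1.737920e-02 1.979577e-01 3.172903e-02
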