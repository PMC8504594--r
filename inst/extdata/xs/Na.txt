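# Photon mass interaction coefficients for Na (Z=11), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 6.522558e+02 1.269920e-02 1.919037e+00 6.541875e+02 6.522558e+02
1.044936e+00 5.790225e+02 1.336155e-02 1.904433e+00 5.809403e+02 5.790225e+02
1.071100e+00 6.429960e+03 1.374857e-02 1.896223e+00 6.431870e+03 6.429960e+03
1.073100e+00 6.406714e+03 1.377818e-02 1.895603e+00 6.408623e+03 6.406714e+03
1.091891e+00 6.194335e+03 1.405651e-02 1.889827e+00 6.196239e+03 6.194335e+03
1.140955e+00 5.685945e+03 1.478357e-02 1.875109e+00 5.687835e+03 5.685945e+03
1.192225e+00 5.214659e+03 1.554186e-02 1.860172e+00 5.216535e+03 5.214659e+03
1.245798e+00 4.775271e+03 1.633010e-02 1.844913e+00 4.777132e+03 4.775271e+03
1.301779e+00 4.363675e+03 1.714659e-02 1.829233e+00 4.365522e+03 4.363675e+03
1.360275e+00 3.976699e+03 1.798912e-02 1.813037e+00 3.978530e+03 3.976699e+03
1.421400e+00 3.611956e+03 1.885499e-02 1.796232e+00 3.613771e+03 3.611956e+03
1.485272e+00 3.267722e+03 1.974090e-02 1.778733e+00 3.269521e+03 3.267722e+03
1.552014e+00 2.943133e+03 2.064363e-02 1.760467e+00 2.944914e+03 2.943133e+03
1.621754e+00 2.639858e+03 2.156468e-02 1.741436e+00 2.641621e+03 2.639858e+03
1.694629e+00 2.359805e+03 2.250863e-02 1.721680e+00 2.361549e+03 2.359805e+03
1.770778e+00 2.103859e+03 2.348092e-02 1.701237e+00 2.105583e+03 2.103859e+03
1.850349e+00 1.872070e+03 2.448792e-02 1.680147e+00 1.873775e+03 1.872070e+03
1.933496e+00 1.663844e+03 2.553705e-02 1.658450e+00 1.665528e+03 1.663844e+03
2.020379e+00 1.478113e+03 2.663681e-02 1.636185e+00 1.479776e+03 1.478113e+03
2.111166e+00 1.313159e+03 2.779455e-02 1.613354e+00 1.314800e+03 1.313159e+03
2.206033e+00 1.166608e+03 2.901339e-02 1.589886e+00 1.168226e+03 1.166608e+03
2.305162e+00 1.036302e+03 3.029599e-02 1.565707e+00 1.037898e+03 1.036302e+03
2.408746e+00 9.203611e+02 3.164508e-02 1.540750e+00 9.219335e+02 9.203613e+02
2.516985e+00 8.171415e+02 3.306343e-02 1.514957e+00 8.186895e+02 8.171417e+02
2.630087e+00 7.252032e+02 3.455386e-02 1.488277e+00 7.267260e+02 7.252034e+02
2.748272e+00 6.432829e+02 3.611924e-02 1.460669e+00 6.447797e+02 6.432831e+02
2.871767e+00 5.702702e+02 3.776247e-02 1.432101e+00 5.717400e+02 5.702704e+02
3.000812e+00 5.051869e+02 3.948647e-02 1.402550e+00 5.066289e+02 5.051871e+02
3.135655e+00 4.471813e+02 4.129383e-02 1.372003e+00 4.485946e+02 4.471816e+02
3.276558e+00 3.955417e+02 4.318570e-02 1.340453e+00 3.969254e+02 3.955420e+02
3.423792e+00 3.496274e+02 4.516253e-02 1.307906e+00 3.509804e+02 3.496277e+02
3.577643e+00 3.088519e+02 4.722431e-02 1.274378e+00 3.101735e+02 3.088523e+02
3.738406e+00 2.726808e+02 4.937052e-02 1.239894e+00 2.739700e+02 2.726811e+02
3.906394e+00 2.406275e+02 5.160003e-02 1.204491e+00 2.418836e+02 2.406279e+02
4.081931e+00 2.122507e+02 5.391112e-02 1.168219e+00 2.134728e+02 2.122511e+02
4.265355e+00 1.871446e+02 5.630176e-02 1.131161e+00 1.883321e+02 1.871451e+02
4.457021e+00 1.649395e+02 5.876967e-02 1.093437e+00 1.660917e+02 1.649400e+02
4.657301e+00 1.453065e+02 6.131194e-02 1.055169e+00 1.464230e+02 1.453070e+02
4.866579e+00 1.279533e+02 6.392495e-02 1.016481e+00 1.290337e+02 1.279539e+02
5.085262e+00 1.126207e+02 6.660427e-02 9.774967e-01 1.136648e+02 1.126214e+02
5.313772e+00 9.907993e+01 6.934433e-02 9.383552e-01 1.000876e+02 9.908063e+01
5.552550e+00 8.712877e+01 7.213823e-02 8.992114e-01 8.810012e+01 8.712954e+01
5.802057e+00 7.658703e+01 7.497802e-02 8.602135e-01 7.752222e+01 7.658786e+01
6.062777e+00 6.729394e+01 7.785461e-02 8.215010e-01 6.819329e+01 6.729484e+01
6.335212e+00 5.910587e+01 8.075852e-02 7.832197e-01 5.996984e+01 5.910684e+01
6.619889e+00 5.189422e+01 8.368096e-02 7.455299e-01 5.272343e+01 5.189527e+01
6.917358e+00 4.554502e+01 8.661245e-02 7.085773e-01 4.634021e+01 4.554615e+01
7.228194e+00 3.995730e+01 8.954271e-02 6.724888e-01 4.071933e+01 3.995853e+01
7.552997e+00 3.504165e+01 9.246077e-02 6.373726e-01 3.577148e+01 3.504297e+01
7.892396e+00 3.071891e+01 9.535491e-02 6.033191e-01 3.141759e+01 3.072034e+01
8.247046e+00 2.691904e+01 9.821317e-02 5.704019e-01 2.758765e+01 2.692057e+01
8.617633e+00 2.358030e+01 1.010257e-01 5.386872e-01 2.422001e+01 2.358194e+01
9.004872e+00 2.064812e+01 1.037843e-01 5.082291e-01 2.126014e+01 2.064988e+01
9.409512e+00 1.807418e+01 1.064809e-01 4.790650e-01 1.865973e+01 1.807607e+01
9.832334e+00 1.581572e+01 1.091074e-01 4.512181e-01 1.637604e+01 1.581773e+01
1.027416e+01 1.383492e+01 1.116560e-01 4.246979e-01 1.437128e+01 1.383707e+01
1.073583e+01 1.209833e+01 1.141217e-01 3.994900e-01 1.261195e+01 1.210063e+01
1.121825e+01 1.057640e+01 1.165021e-01 3.755650e-01 1.106846e+01 1.057884e+01
1.172235e+01 9.243054e+00 1.187951e-01 3.528893e-01 9.714738e+00 9.245649e+00
1.224911e+01 8.075351e+00 1.209993e-01 3.314263e-01 8.527776e+00 8.078106e+00
1.279953e+01 7.053064e+00 1.231141e-01 3.111369e-01 7.487315e+00 7.055987e+00
1.337468e+01 6.158390e+00 1.251392e-01 2.919801e-01 6.575510e+00 6.161488e+00
1.397568e+01 5.375662e+00 1.270750e-01 2.739131e-01 5.776651e+00 5.378941e+00
1.460369e+01 4.691099e+00 1.289225e-01 2.568925e-01 5.076914e+00 4.694566e+00
1.525992e+01 4.092579e+00 1.306830e-01 2.408738e-01 4.464136e+00 4.096242e+00
1.594563e+01 3.569447e+00 1.323586e-01 2.258065e-01 3.927612e+00 3.573313e+00
1.666216e+01 3.112342e+00 1.339514e-01 2.116342e-01 3.457927e+00 3.116418e+00
1.741088e+01 2.713042e+00 1.354643e-01 1.983035e-01 3.046810e+00 2.717337e+00
1.819325e+01 2.364336e+00 1.369003e-01 1.857647e-01 2.687001e+00 2.368858e+00
1.901078e+01 2.059900e+00 1.382631e-01 1.739709e-01 2.372134e+00 2.064656e+00
1.986504e+01 1.794185e+00 1.395566e-01 1.628785e-01 2.096621e+00 1.799185e+00
2.075769e+01 1.562356e+00 1.407843e-01 1.524470e-01 1.855587e+00 1.567608e+00
2.169045e+01 1.360131e+00 1.419467e-01 1.426339e-01 1.644712e+00 1.365644e+00
2.266512e+01 1.183781e+00 1.430427e-01 1.333997e-01 1.460224e+00 1.189565e+00
2.368360e+01 1.030041e+00 1.440713e-01 1.247082e-01 1.298820e+00 1.036103e+00
2.474783e+01 8.960496e-01 1.450318e-01 1.165262e-01 1.157608e+00 9.024010e-01
2.585989e+01 7.793042e-01 1.459234e-01 1.088229e-01 1.034050e+00 7.859534e-01
2.702193e+01 6.776130e-01 1.467455e-01 1.015700e-01 9.259284e-01 6.845693e-01
2.823617e+01 5.890589e-01 1.474976e-01 9.474111e-02 8.312977e-01 5.963315e-01
2.950498e+01 5.119653e-01 1.481795e-01 8.831201e-02 7.484568e-01 5.195633e-01
3.083081e+01 4.448511e-01 1.487910e-01 8.225883e-02 6.759009e-01 4.527838e-01
3.221621e+01 3.864468e-01 1.493311e-01 7.656432e-02 6.123422e-01 3.947231e-01
3.366387e+01 3.356430e-01 1.497984e-01 7.121382e-02 5.566552e-01 3.442718e-01
3.517658e+01 2.914613e-01 1.501919e-01 6.619183e-02 5.078451e-01 3.004513e-01
3.675726e+01 2.530479e-01 1.505104e-01 6.148298e-02 4.650413e-01 2.624075e-01
3.840897e+01 2.196574e-01 1.507530e-01 5.707215e-02 4.274825e-01 2.293947e-01
4.013491e+01 1.906406e-01 1.509188e-01 5.294462e-02 3.945040e-01 2.007634e-01
4.193839e+01 1.654408e-01 1.510070e-01 4.908752e-02 3.655352e-01 1.759565e-01
4.382292e+01 1.435502e-01 1.510181e-01 4.548498e-02 3.400533e-01 1.544659e-01
4.579214e+01 1.245394e-01 1.509525e-01 4.212351e-02 3.176153e-01 1.358617e-01
4.784984e+01 1.080333e-01 1.508108e-01 3.898995e-02 2.978341e-01 1.197687e-01
5.000000e+01 9.370538e-02 1.505938e-01 3.607153e-02 2.803707e-01 1.058595e-01
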