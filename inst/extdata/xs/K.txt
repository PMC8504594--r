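# Photon mass interaction coefficients for K (Z=19), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 4.054006e+03 1.215559e-02 3.346987e+00 4.057365e+03 4.054006e+03
1.044936e+00 3.616804e+03 1.280811e-02 3.320303e+00 3.620137e+03 3.616804e+03
1.091891e+00 3.226747e+03 1.349506e-02 3.293585e+00 3.230054e+03 3.226747e+03
1.140955e+00 2.878756e+03 1.421756e-02 3.266597e+00 2.882037e+03 2.878756e+03
1.192225e+00 2.568295e+03 1.497674e-02 3.239106e+00 2.571549e+03 2.568295e+03
1.245798e+00 2.291315e+03 1.577363e-02 3.210890e+00 2.294542e+03 2.291315e+03
1.301779e+00 2.044206e+03 1.660919e-02 3.181737e+00 2.047405e+03 2.044206e+03
1.360275e+00 1.823747e+03 1.748431e-02 3.151441e+00 1.826916e+03 1.823748e+03
1.421400e+00 1.627064e+03 1.839977e-02 3.119808e+00 1.630202e+03 1.627064e+03
1.485272e+00 1.451592e+03 1.935622e-02 3.086654e+00 1.454698e+03 1.451592e+03
1.552014e+00 1.291815e+03 2.035430e-02 3.051818e+00 1.294887e+03 1.291815e+03
1.621754e+00 1.148794e+03 2.139563e-02 3.015248e+00 1.151831e+03 1.148794e+03
1.694629e+00 1.021608e+03 2.248241e-02 2.976942e+00 1.024607e+03 1.021608e+03
1.770778e+00 9.085022e+02 2.361705e-02 2.936907e+00 9.114628e+02 9.085023e+02
1.850349e+00 8.079191e+02 2.480218e-02 2.895153e+00 8.108391e+02 8.079192e+02
1.933496e+00 7.184719e+02 2.604062e-02 2.851701e+00 7.213496e+02 7.184720e+02
2.020379e+00 6.385705e+02 2.733543e-02 2.806577e+00 6.414044e+02 6.385706e+02
2.111166e+00 5.664976e+02 2.868904e-02 2.759798e+00 5.692861e+02 5.664977e+02
2.206033e+00 5.025593e+02 3.010216e-02 2.711355e+00 5.053008e+02 5.025594e+02
2.305162e+00 4.458375e+02 3.157497e-02 2.661245e+00 4.485303e+02 4.458376e+02
2.408746e+00 3.955176e+02 3.310734e-02 2.609481e+00 3.981602e+02 3.955178e+02
2.516985e+00 3.508771e+02 3.469873e-02 2.556081e+00 3.534679e+02 3.508773e+02
2.630087e+00 3.112751e+02 3.634822e-02 2.501079e+00 3.138125e+02 3.112752e+02
2.748272e+00 2.761427e+02 3.805442e-02 2.444519e+00 2.786253e+02 2.761429e+02
2.871767e+00 2.449756e+02 3.981546e-02 2.386457e+00 2.474019e+02 2.449758e+02
3.000812e+00 2.173240e+02 4.162890e-02 2.326959e+00 2.196926e+02 2.173243e+02
3.135655e+00 1.924838e+02 4.349219e-02 2.266133e+00 1.947934e+02 1.924841e+02
3.276558e+00 1.704828e+02 4.540360e-02 2.204212e+00 1.727324e+02 1.704831e+02
3.423792e+00 1.509965e+02 4.736151e-02 2.141449e+00 1.531853e+02 1.509968e+02
3.577643e+00 1.337375e+02 4.936403e-02 2.078088e+00 1.358650e+02 1.337379e+02
3.606400e+00 1.308134e+02 4.973340e-02 2.066501e+00 1.329296e+02 1.308137e+02
3.608400e+00 1.306133e+02 4.975904e-02 2.065698e+00 1.327287e+02 1.306136e+02
3.738406e+00 1.096268e+03 5.140901e-02 2.014358e+00 1.098334e+03 1.096268e+03
3.906394e+00 9.808773e+02 5.349398e-02 1.950479e+00 9.828813e+02 9.808777e+02
4.081931e+00 8.768989e+02 5.561619e-02 1.886658e+00 8.788412e+02 8.768993e+02
4.265355e+00 7.831512e+02 5.777202e-02 1.823107e+00 7.850321e+02 7.831517e+02
4.457021e+00 6.988190e+02 5.995683e-02 1.760042e+00 7.006390e+02 6.988196e+02
4.657301e+00 6.231244e+02 6.216548e-02 1.697659e+00 6.248842e+02 6.231249e+02
4.866579e+00 5.553204e+02 6.439233e-02 1.636138e+00 5.570209e+02 5.553210e+02
5.085262e+00 4.946963e+02 6.663122e-02 1.575638e+00 4.963386e+02 4.946970e+02
5.313772e+00 4.405387e+02 6.887641e-02 1.516334e+00 4.421239e+02 4.405394e+02
5.552550e+00 3.921434e+02 7.112299e-02 1.458420e+00 3.936729e+02 3.921442e+02
5.802057e+00 3.488855e+02 7.336593e-02 1.402065e+00 3.503609e+02 3.488863e+02
6.062777e+00 3.102130e+02 7.559999e-02 1.347412e+00 3.116360e+02 3.102139e+02
6.335212e+00 2.756472e+02 7.782085e-02 1.294528e+00 2.770196e+02 2.756481e+02
6.619889e+00 2.447765e+02 8.002640e-02 1.243370e+00 2.460999e+02 2.447775e+02
6.917358e+00 2.172296e+02 8.221498e-02 1.193888e+00 2.185057e+02 2.172307e+02
7.228194e+00 1.926691e+02 8.438525e-02 1.146032e+00 1.938995e+02 1.926702e+02
7.552997e+00 1.707887e+02 8.653609e-02 1.099754e+00 1.719750e+02 1.707900e+02
7.892396e+00 1.513113e+02 8.866670e-02 1.055007e+00 1.524549e+02 1.513126e+02
8.247046e+00 1.339853e+02 9.077686e-02 1.011741e+00 1.350878e+02 1.339867e+02
8.617633e+00 1.185825e+02 9.286776e-02 9.698312e-01 1.196452e+02 1.185840e+02
9.004872e+00 1.048968e+02 9.494191e-02 9.291281e-01 1.059209e+02 1.048984e+02
9.409512e+00 9.274301e+01 9.700238e-02 8.895011e-01 9.372952e+01 9.274473e+01
9.832334e+00 8.195535e+01 9.905276e-02 8.508395e-01 8.290524e+01 8.195718e+01
1.027416e+01 7.238539e+01 1.010967e-01 8.130546e-01 7.329954e+01 7.238734e+01
1.073583e+01 6.390074e+01 1.031348e-01 7.761084e-01 6.477998e+01 6.390281e+01
1.121825e+01 5.638309e+01 1.051648e-01 7.399964e-01 5.722825e+01 5.638529e+01
1.172235e+01 4.972641e+01 1.071842e-01 7.047192e-01 5.053831e+01 4.972875e+01
1.224911e+01 4.383567e+01 1.091907e-01 6.702803e-01 4.461514e+01 4.383816e+01
1.279953e+01 3.862582e+01 1.111817e-01 6.366859e-01 3.937369e+01 3.862846e+01
1.337468e+01 3.402080e+01 1.131548e-01 6.039445e-01 3.473790e+01 3.402360e+01
1.397568e+01 2.995264e+01 1.151073e-01 5.720665e-01 3.063982e+01 2.995561e+01
1.460369e+01 2.636069e+01 1.170366e-01 5.410636e-01 2.701879e+01 2.636384e+01
1.525992e+01 2.319081e+01 1.189401e-01 5.109491e-01 2.382070e+01 2.319414e+01
1.594563e+01 2.039460e+01 1.208135e-01 4.817745e-01 2.099719e+01 2.039813e+01
1.666216e+01 1.792886e+01 1.226503e-01 4.536296e-01 1.850514e+01 1.793259e+01
1.741088e+01 1.575522e+01 1.244437e-01 4.265874e-01 1.630626e+01 1.575917e+01
1.819325e+01 1.383974e+01 1.261866e-01 4.007018e-01 1.436663e+01 1.384391e+01
1.901078e+01 1.215233e+01 1.278718e-01 3.760094e-01 1.265621e+01 1.215673e+01
1.986504e+01 1.066636e+01 1.294918e-01 3.525313e-01 1.114838e+01 1.067100e+01
2.075769e+01 9.358382e+00 1.310398e-01 3.302750e-01 9.819697e+00 9.363270e+00
2.169045e+01 8.207556e+00 1.325127e-01 3.092170e-01 8.649286e+00 8.212703e+00
2.266512e+01 7.195513e+00 1.339091e-01 2.893244e-01 7.618747e+00 7.200927e+00
2.368360e+01 6.305971e+00 1.352280e-01 2.705612e-01 6.711760e+00 6.311662e+00
2.474783e+01 5.524485e+00 1.364685e-01 2.528889e-01 5.913843e+00 5.530462e+00
2.585989e+01 4.838255e+00 1.376298e-01 2.362668e-01 5.212152e+00 4.844527e+00
2.702193e+01 4.235945e+00 1.387116e-01 2.206526e-01 4.595309e+00 4.242520e+00
2.823617e+01 3.707523e+00 1.397134e-01 2.060031e-01 4.053239e+00 3.714411e+00
2.950498e+01 3.244118e+00 1.406352e-01 1.922745e-01 3.577028e+00 3.251329e+00
3.083081e+01 2.837802e+00 1.414771e-01 1.794191e-01 3.158698e+00 2.845345e+00
3.221621e+01 2.481686e+00 1.422399e-01 1.673866e-01 2.791313e+00 2.489569e+00
3.366387e+01 2.169687e+00 1.429249e-01 1.561240e-01 2.468736e+00 2.177920e+00
3.517658e+01 1.896400e+00 1.435336e-01 1.455806e-01 2.185514e+00 1.904992e+00
3.675726e+01 1.657079e+00 1.440676e-01 1.357092e-01 1.936855e+00 1.666037e+00
3.840897e+01 1.447550e+00 1.445288e-01 1.264663e-01 1.718546e+00 1.456886e+00
4.013491e+01 1.264159e+00 1.449192e-01 1.178118e-01 1.526890e+00 1.273879e+00
4.193839e+01 1.103757e+00 1.452404e-01 1.097115e-01 1.358709e+00 1.113871e+00
4.382292e+01 9.634476e-01 1.454924e-01 1.021261e-01 1.211066e+00 9.739639e-01
4.579214e+01 8.407670e-01 1.456750e-01 9.502288e-02 1.081465e+00 8.516936e-01
4.784984e+01 7.335436e-01 1.457882e-01 8.837178e-02 9.677036e-01 7.448881e-01
5.000000e+01 6.398654e-01 1.458320e-01 8.214463e-02 8.678420e-01 6.516352e-01
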