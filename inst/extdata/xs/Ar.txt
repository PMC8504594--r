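# Photon mass interaction coefficients for Ar (Z=18), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 3.180839e+03 7.079099e-03 3.042138e+00 3.183888e+03 3.180825e+03
1.044936e+00 2.835495e+03 7.649324e-03 3.021807e+00 2.838525e+03 2.835483e+03
1.091891e+00 2.527641e+03 8.264303e-03 3.001304e+00 2.530650e+03 2.527630e+03
1.140955e+00 2.253210e+03 8.926185e-03 2.980330e+00 2.256199e+03 2.253201e+03
1.192225e+00 2.008575e+03 9.636964e-03 2.958592e+00 2.011543e+03 2.008568e+03
1.245798e+00 1.790501e+03 1.039843e-02 2.935810e+00 1.793447e+03 1.790494e+03
1.301779e+00 1.596103e+03 1.121208e-02 2.911712e+00 1.599026e+03 1.596097e+03
1.360275e+00 1.422811e+03 1.207909e-02 2.886037e+00 1.425709e+03 1.422806e+03
1.421400e+00 1.268334e+03 1.300019e-02 2.858537e+00 1.271205e+03 1.268330e+03
1.485272e+00 1.130629e+03 1.397563e-02 2.828980e+00 1.133472e+03 1.130625e+03
1.552014e+00 1.005568e+03 1.500520e-02 2.797165e+00 1.008380e+03 1.005565e+03
1.621754e+00 8.937483e+02 1.608949e-02 2.763054e+00 8.965275e+02 8.937459e+02
1.694629e+00 7.943628e+02 1.722949e-02 2.726688e+00 7.971067e+02 7.943608e+02
1.770778e+00 7.060291e+02 1.842603e-02 2.688115e+00 7.087356e+02 7.060273e+02
1.850349e+00 6.275181e+02 1.967978e-02 2.647393e+00 6.301852e+02 6.275166e+02
1.933496e+00 5.577376e+02 2.099119e-02 2.604584e+00 5.603632e+02 5.577364e+02
2.020379e+00 4.954639e+02 2.236052e-02 2.559764e+00 4.980460e+02 4.954629e+02
2.111166e+00 4.393952e+02 2.378778e-02 2.513017e+00 4.419320e+02 4.393944e+02
2.206033e+00 3.896715e+02 2.527262e-02 2.464443e+00 3.921612e+02 3.896708e+02
2.305162e+00 3.455747e+02 2.681443e-02 2.414151e+00 3.480157e+02 3.455741e+02
2.408746e+00 3.064681e+02 2.841227e-02 2.362255e+00 3.088587e+02 3.064676e+02
2.516985e+00 2.717869e+02 3.006489e-02 2.308872e+00 2.741258e+02 2.717866e+02
2.630087e+00 2.410304e+02 3.177072e-02 2.254127e+00 2.433163e+02 2.410302e+02
2.748272e+00 2.137544e+02 3.352783e-02 2.198146e+00 2.159861e+02 2.137543e+02
2.871767e+00 1.895651e+02 3.533393e-02 2.141059e+00 1.917415e+02 1.895650e+02
3.000812e+00 1.681134e+02 3.718639e-02 2.082999e+00 1.702336e+02 1.681134e+02
3.135655e+00 1.491220e+02 3.908226e-02 2.024124e+00 1.511852e+02 1.491220e+02
3.205000e+00 1.404864e+02 4.004103e-02 1.994599e+00 1.425211e+02 1.404865e+02
3.207000e+00 1.271939e+03 4.006852e-02 1.993755e+00 1.273973e+03 1.146837e+03
3.276558e+00 1.210879e+03 4.101873e-02 1.964684e+00 1.212884e+03 1.094310e+03
3.423792e+00 1.094424e+03 4.299278e-02 1.904935e+00 1.096372e+03 9.935972e+02
3.577643e+00 9.881550e+02 4.500115e-02 1.845118e+00 9.900451e+02 9.010332e+02
3.738406e+00 8.906779e+02 4.704034e-02 1.785456e+00 8.925104e+02 8.155273e+02
3.906394e+00 8.008932e+02 4.910662e-02 1.726154e+00 8.026684e+02 7.362242e+02
4.081931e+00 7.179583e+02 5.119608e-02 1.667401e+00 7.196769e+02 6.624791e+02
4.265355e+00 6.416279e+02 5.330413e-02 1.609393e+00 6.432906e+02 5.941793e+02
4.457021e+00 5.720326e+02 5.542540e-02 1.552326e+00 5.736403e+02 5.315498e+02
4.657301e+00 5.091224e+02 5.755421e-02 1.496379e+00 5.106764e+02 4.746413e+02
4.866579e+00 4.526871e+02 5.968459e-02 1.441703e+00 4.541885e+02 4.233467e+02
5.085262e+00 4.023969e+02 6.181027e-02 1.388429e+00 4.038471e+02 3.774377e+02
5.313772e+00 3.577141e+02 6.392647e-02 1.336640e+00 3.591147e+02 3.364807e+02
5.552550e+00 3.179570e+02 6.603083e-02 1.286365e+00 3.193094e+02 2.998953e+02
5.802057e+00 2.825277e+02 6.812146e-02 1.237626e+00 2.838335e+02 2.671689e+02
6.062777e+00 2.509140e+02 7.019683e-02 1.190433e+00 2.521746e+02 2.378605e+02
6.335212e+00 2.226907e+02 7.225591e-02 1.144763e+00 2.239077e+02 2.116039e+02
6.619889e+00 1.975124e+02 7.429857e-02 1.100531e+00 1.986872e+02 1.881022e+02
6.917358e+00 1.750705e+02 7.632509e-02 1.057651e+00 1.762045e+02 1.670884e+02
7.228194e+00 1.550848e+02 7.833625e-02 1.016050e+00 1.561792e+02 1.483182e+02
7.552997e+00 1.373012e+02 8.033331e-02 9.756579e-01 1.383572e+02 1.315684e+02
7.892396e+00 1.214897e+02 8.231797e-02 9.364155e-01 1.225084e+02 1.166354e+02
8.247046e+00 1.074418e+02 8.429243e-02 8.982622e-01 1.084244e+02 1.033338e+02
8.617633e+00 9.496962e+01 8.625849e-02 8.610912e-01 9.591697e+01 9.149488e+01
9.004872e+00 8.390335e+01 8.821790e-02 8.247796e-01 8.481635e+01 8.096584e+01
9.409512e+00 7.409046e+01 9.017279e-02 7.892238e-01 7.496986e+01 7.160838e+01
9.832334e+00 6.539411e+01 9.212566e-02 7.543392e-01 6.624058e+01 6.329793e+01
1.027416e+01 5.769185e+01 9.407903e-02 7.200640e-01 5.850599e+01 5.592246e+01
1.073583e+01 5.087372e+01 9.603222e-02 6.864080e-01 5.165617e+01 4.938094e+01
1.121825e+01 4.484137e+01 9.798187e-02 6.534253e-01 4.559278e+01 4.358260e+01
1.172235e+01 3.950701e+01 9.992433e-02 6.211667e-01 4.022810e+01 3.844613e+01
1.224911e+01 3.479229e+01 1.018558e-01 5.896784e-01 3.548383e+01 3.389867e+01
1.279953e+01 3.062733e+01 1.037723e-01 5.590022e-01 3.129010e+01 2.987502e+01
1.337468e+01 2.694983e+01 1.056696e-01 5.291748e-01 2.758468e+01 2.631687e+01
1.397568e+01 2.370433e+01 1.075436e-01 5.002287e-01 2.431210e+01 2.317210e+01
1.460369e+01 2.084142e+01 1.093897e-01 4.721912e-01 2.142300e+01 2.039420e+01
1.525992e+01 1.831717e+01 1.112034e-01 4.450861e-01 1.887346e+01 1.794166e+01
1.594563e+01 1.609248e+01 1.129798e-01 4.189576e-01 1.662442e+01 1.577745e+01
1.666216e+01 1.413261e+01 1.147132e-01 3.938717e-01 1.464119e+01 1.386856e+01
1.741088e+01 1.240672e+01 1.163976e-01 3.698784e-01 1.289300e+01 1.218564e+01
1.819325e+01 1.088749e+01 1.180272e-01 3.470112e-01 1.135253e+01 1.070262e+01
1.901078e+01 9.550693e+00 1.195960e-01 3.252889e-01 9.995578e+00 9.396341e+00
1.986504e+01 8.374888e+00 1.210978e-01 3.047173e-01 8.800703e+00 8.246246e+00
2.075769e+01 7.341204e+00 1.225269e-01 2.852897e-01 7.749020e+00 7.234220e+00
2.169045e+01 6.432787e+00 1.238814e-01 2.669685e-01 6.823637e+00 6.344052e+00
2.266512e+01 5.634813e+00 1.251608e-01 2.497081e-01 6.009682e+00 5.561455e+00
2.368360e+01 4.934171e+00 1.263649e-01 2.334631e-01 5.293999e+00 4.873773e+00
2.474783e+01 4.319256e+00 1.274935e-01 2.181882e-01 4.664938e+00 4.269787e+00
2.585989e+01 3.779807e+00 1.285471e-01 2.038382e-01 4.112193e+00 3.739560e+00
2.702193e+01 3.306757e+00 1.295260e-01 1.903689e-01 3.626652e+00 3.274297e+00
2.823617e+01 2.892094e+00 1.304308e-01 1.777364e-01 3.200262e+00 2.866218e+00
2.950498e+01 2.528752e+00 1.312623e-01 1.658980e-01 2.825912e+00 2.508448e+00
3.083081e+01 2.210418e+00 1.320217e-01 1.548091e-01 2.497249e+00 2.194842e+00
3.221621e+01 1.931630e+00 1.327099e-01 1.444251e-01 2.208764e+00 1.920072e+00
3.366387e+01 1.687567e+00 1.333274e-01 1.347010e-01 1.955595e+00 1.679434e+00
3.517658e+01 1.473952e+00 1.338751e-01 1.255937e-01 1.733421e+00 1.468748e+00
3.675726e+01 1.287030e+00 1.343541e-01 1.170631e-01 1.538447e+00 1.284340e+00
3.840897e+01 1.123503e+00 1.347656e-01 1.090720e-01 1.367341e+00 1.122981e+00
4.013491e+01 9.804845e-01 1.351109e-01 1.015865e-01 1.217182e+00 9.818412e-01
4.193839e+01 8.554900e-01 1.353910e-01 9.457743e-02 1.085458e+00 8.584839e-01
4.382292e+01 7.462365e-01 1.356066e-01 8.801134e-02 9.698544e-01 7.506670e-01
4.579214e+01 6.507827e-01 1.357580e-01 8.186057e-02 8.684013e-01 6.564826e-01
4.784984e+01 5.674193e-01 1.358459e-01 7.609943e-02 7.793646e-01 5.742496e-01
5.000000e+01 4.946424e-01 1.358709e-01 7.070397e-02 7.012173e-01 5.024878e-01
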