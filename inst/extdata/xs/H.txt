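# Photon mass interaction coefficients for H (Z=1), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 6.817515e+00 5.033229e-02 3.468444e-01 7.214692e+00 6.817613e+00
1.044936e+00 5.885133e+00 5.427318e-02 3.421215e-01 6.281528e+00 5.885244e+00
1.091891e+00 5.080176e+00 5.851217e-02 3.373954e-01 5.476083e+00 5.080300e+00
1.140955e+00 4.385169e+00 6.305972e-02 3.326017e-01 4.780830e+00 4.385309e+00
1.192225e+00 3.785050e+00 6.792432e-02 3.276799e-01 4.180654e+00 3.785208e+00
1.245798e+00 3.266835e+00 7.311195e-02 3.225733e-01 3.662520e+00 3.267012e+00
1.301779e+00 2.819328e+00 7.862557e-02 3.172295e-01 3.215183e+00 2.819527e+00
1.360275e+00 2.432873e+00 8.446446e-02 3.116008e-01 2.828938e+00 2.433096e+00
1.421400e+00 2.099139e+00 9.062363e-02 3.056445e-01 2.495407e+00 2.099389e+00
1.485272e+00 1.810937e+00 9.709315e-02 2.993238e-01 2.207354e+00 1.811218e+00
1.552014e+00 1.562068e+00 1.038585e-01 2.926114e-01 1.958538e+00 1.562381e+00
1.621754e+00 1.347192e+00 1.109089e-01 2.855187e-01 1.743620e+00 1.347542e+00
1.694629e+00 1.161701e+00 1.182345e-01 2.780754e-01 1.558011e+00 1.162090e+00
1.770778e+00 1.001605e+00 1.258223e-01 2.703126e-01 1.397739e+00 1.002037e+00
1.850349e+00 8.634504e-01 1.336564e-01 2.622629e-01 1.259370e+00 8.639305e-01
1.933496e+00 7.442516e-01 1.417171e-01 2.539600e-01 1.139929e+00 7.447834e-01
2.020379e+00 6.414247e-01 1.499815e-01 2.454387e-01 1.036845e+00 6.420126e-01
2.111166e+00 5.527368e-01 1.584240e-01 2.367355e-01 9.478964e-01 5.533854e-01
2.206033e+00 4.762564e-01 1.670166e-01 2.278894e-01 8.711624e-01 4.769707e-01
2.305162e+00 4.103147e-01 1.757285e-01 2.189391e-01 8.049823e-01 4.110996e-01
2.408746e+00 3.534686e-01 1.845260e-01 2.099226e-01 7.479172e-01 3.543295e-01
2.516985e+00 3.044713e-01 1.933722e-01 2.008769e-01 6.987204e-01 3.054136e-01
2.630087e+00 2.622451e-01 2.022276e-01 1.918378e-01 6.563105e-01 2.632743e-01
2.748272e+00 2.258593e-01 2.110499e-01 1.828395e-01 6.197487e-01 2.269811e-01
2.871767e+00 1.945100e-01 2.197945e-01 1.739145e-01 5.882191e-01 1.957302e-01
3.000812e+00 1.675033e-01 2.284148e-01 1.650934e-01 5.610116e-01 1.688276e-01
3.135655e+00 1.442394e-01 2.368655e-01 1.564081e-01 5.375130e-01 1.456736e-01
3.276558e+00 1.241993e-01 2.451148e-01 1.478990e-01 5.172131e-01 1.257492e-01
3.423792e+00 1.069357e-01 2.531353e-01 1.396041e-01 4.996751e-01 1.086071e-01
3.577643e+00 9.206349e-02 2.609020e-01 1.315551e-01 4.845206e-01 9.386245e-02
3.738406e+00 7.925145e-02 2.683915e-01 1.237781e-01 4.714212e-01 8.118390e-02
3.906394e+00 6.821428e-02 2.755832e-01 1.162939e-01 4.600914e-01 7.028620e-02
4.081931e+00 5.870629e-02 2.824590e-01 1.091178e-01 4.502831e-01 6.092368e-02
4.265355e+00 5.051665e-02 2.890073e-01 1.022587e-01 4.417826e-01 5.288556e-02
4.457021e+00 4.346424e-02 2.952240e-01 9.571934e-02 4.344076e-01 4.599080e-02
4.657301e+00 3.739242e-02 3.011085e-01 8.950002e-02 4.280010e-01 4.008287e-02
4.866579e+00 3.216589e-02 3.066637e-01 8.359858e-02 4.224282e-01 3.502658e-02
5.085262e+00 2.766782e-02 3.118953e-01 7.801093e-02 4.175741e-01 3.070526e-02
5.313772e+00 2.379770e-02 3.168099e-01 7.273117e-02 4.133388e-01 2.701855e-02
5.552550e+00 2.046899e-02 3.214139e-01 6.775181e-02 4.096347e-01 2.388006e-02
5.802057e+00 1.760684e-02 3.257158e-01 6.306422e-02 4.063869e-01 2.121512e-02
6.062777e+00 1.514651e-02 3.297261e-01 5.865888e-02 4.035314e-01 1.895919e-02
6.335212e+00 1.303164e-02 3.334549e-01 5.452483e-02 4.010114e-01 1.705611e-02
6.619889e+00 1.121290e-02 3.369112e-01 5.064902e-02 3.987731e-01 1.545676e-02
6.917358e+00 9.648182e-03 3.401042e-01 4.701862e-02 3.967710e-01 1.411922e-02
7.228194e+00 8.301512e-03 3.430447e-01 4.362115e-02 3.949674e-01 1.300775e-02
7.552997e+00 7.142150e-03 3.457446e-01 4.044443e-02 3.933311e-01 1.209188e-02
7.892396e+00 6.143795e-03 3.482168e-01 3.747665e-02 3.918372e-01 1.134560e-02
8.247046e+00 5.283922e-03 3.504757e-01 3.470629e-02 3.904659e-01 1.074669e-02
8.617633e+00 4.543519e-03 3.525309e-01 3.212239e-02 3.891968e-01 1.027644e-02
9.004872e+00 3.906283e-03 3.543897e-01 2.971439e-02 3.880103e-01 9.918779e-03
9.409512e+00 3.358064e-03 3.560603e-01 2.747209e-02 3.868905e-01 9.659830e-03
9.832334e+00 2.886598e-03 3.575517e-01 2.538568e-02 3.858240e-01 9.487625e-03
1.027416e+01 2.481273e-03 3.588724e-01 2.344582e-02 3.847995e-01 9.391848e-03
1.073583e+01 2.132849e-03 3.600298e-01 2.164356e-02 3.838062e-01 9.363551e-03
1.121825e+01 1.833330e-03 3.610303e-01 1.997035e-02 3.828340e-01 9.395014e-03
1.172235e+01 1.575849e-03 3.618802e-01 1.841806e-02 3.818741e-01 9.479650e-03
1.224911e+01 1.354505e-03 3.625859e-01 1.697896e-02 3.809194e-01 9.611851e-03
1.279953e+01 1.164224e-03 3.631542e-01 1.564571e-02 3.799641e-01 9.786850e-03
1.337468e+01 1.000648e-03 3.635919e-01 1.441133e-02 3.790039e-01 1.000061e-02
1.397568e+01 8.600287e-04 3.639063e-01 1.326921e-02 3.780355e-01 1.024972e-02
1.460369e+01 7.391456e-04 3.641046e-01 1.221310e-02 3.770568e-01 1.053132e-02
1.525992e+01 6.352292e-04 3.641942e-01 1.123710e-02 3.760666e-01 1.084300e-02
1.594563e+01 5.459013e-04 3.641805e-01 1.033564e-02 3.750621e-01 1.118273e-02
1.666216e+01 4.691198e-04 3.640658e-01 9.503507e-03 3.740384e-01 1.154869e-02
1.741088e+01 4.031268e-04 3.638522e-01 8.735778e-03 3.729911e-01 1.193936e-02
1.819325e+01 3.464097e-04 3.635422e-01 8.027832e-03 3.719165e-01 1.235347e-02
1.901078e+01 2.976675e-04 3.631382e-01 7.375337e-03 3.708112e-01 1.278993e-02
1.986504e+01 2.557808e-04 3.626426e-01 6.774233e-03 3.696726e-01 1.324783e-02
2.075769e+01 2.197901e-04 3.620581e-01 6.220776e-03 3.684987e-01 1.372643e-02
2.169045e+01 1.888630e-04 3.613867e-01 5.711345e-03 3.672869e-01 1.422506e-02
2.266512e+01 1.622868e-04 3.606305e-01 5.242601e-03 3.660354e-01 1.474318e-02
2.368360e+01 1.394493e-04 3.597916e-01 4.811446e-03 3.647425e-01 1.528031e-02
2.474783e+01 1.198246e-04 3.588723e-01 4.415000e-03 3.634071e-01 1.583607e-02
2.585989e+01 1.029609e-04 3.578746e-01 4.050587e-03 3.620282e-01 1.641011e-02
2.702193e+01 8.846972e-05 3.568009e-01 3.715722e-03 3.606051e-01 1.700214e-02
2.823617e+01 7.601735e-05 3.556534e-01 3.408100e-03 3.591375e-01 1.761190e-02
2.950498e+01 6.531700e-05 3.544344e-01 3.125584e-03 3.576253e-01 1.823916e-02
3.083081e+01 5.612014e-05 3.531461e-01 2.866133e-03 3.560683e-01 1.888369e-02
3.221621e+01 4.821676e-05 3.517891e-01 2.627938e-03 3.544653e-01 1.954520e-02
3.366387e+01 4.142635e-05 3.503632e-01 2.409326e-03 3.528140e-01 2.022333e-02
3.517658e+01 3.559242e-05 3.488679e-01 2.208716e-03 3.511122e-01 2.091768e-02
3.675726e+01 3.058039e-05 3.473029e-01 2.024651e-03 3.493582e-01 2.162784e-02
3.840897e+01 2.627459e-05 3.456681e-01 1.855792e-03 3.475501e-01 2.235336e-02
4.013491e+01 2.257572e-05 3.439631e-01 1.700907e-03 3.456866e-01 2.309374e-02
4.193839e+01 1.939958e-05 3.421883e-01 1.558920e-03 3.437666e-01 2.384847e-02
4.382292e+01 1.667089e-05 3.403448e-01 1.428704e-03 3.417902e-01 2.461705e-02
4.579214e+01 1.432662e-05 3.384341e-01 1.309297e-03 3.397578e-01 2.539898e-02
4.784984e+01 1.231262e-05 3.364576e-01 1.199813e-03 3.376698e-01 2.619371e-02
5.000000e+01 1.058233e-05 3.344169e-01 1.099437e-03 3.355269e-01 2.700063e-02
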