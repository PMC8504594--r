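# Photon mass interaction coefficients for O (Z=8), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 4.588331e+03 8.514038e-03 1.501450e+00 4.589841e+03 4.588331e+03
1.044936e+00 4.083344e+03 9.229784e-03 1.491437e+00 4.084845e+03 4.083344e+03
1.091891e+00 3.633612e+03 1.000462e-02 1.481329e+00 3.635103e+03 3.633612e+03
1.140955e+00 3.232844e+03 1.084217e-02 1.470971e+00 3.234326e+03 3.232844e+03
1.192225e+00 2.875519e+03 1.174605e-02 1.460210e+00 2.876991e+03 2.875519e+03
1.245798e+00 2.556788e+03 1.271980e-02 1.448899e+00 2.558250e+03 2.556788e+03
1.301779e+00 2.272386e+03 1.376687e-02 1.436897e+00 2.273837e+03 2.272386e+03
1.360275e+00 2.018553e+03 1.489051e-02 1.424066e+00 2.019992e+03 2.018553e+03
1.421400e+00 1.791970e+03 1.609373e-02 1.410280e+00 1.793396e+03 1.791970e+03
1.485272e+00 1.589701e+03 1.737921e-02 1.395415e+00 1.591114e+03 1.589701e+03
1.552014e+00 1.409163e+03 1.874933e-02 1.379368e+00 1.410561e+03 1.409163e+03
1.621754e+00 1.248170e+03 2.020698e-02 1.362102e+00 1.249553e+03 1.248170e+03
1.694629e+00 1.104785e+03 2.175532e-02 1.343619e+00 1.106150e+03 1.104785e+03
1.770778e+00 9.772318e+02 2.339735e-02 1.323925e+00 9.785792e+02 9.772319e+02
1.850349e+00 8.638896e+02 2.513583e-02 1.303032e+00 8.652178e+02 8.638897e+02
1.933496e+00 7.632809e+02 2.697329e-02 1.280959e+00 7.645888e+02 7.632810e+02
2.020379e+00 6.740637e+02 2.891191e-02 1.257731e+00 6.753504e+02 6.740638e+02
2.111166e+00 5.950117e+02 3.095332e-02 1.233375e+00 5.962760e+02 5.950118e+02
2.206033e+00 5.249987e+02 3.309823e-02 1.207912e+00 5.262397e+02 5.249988e+02
2.305162e+00 4.630184e+02 3.534666e-02 1.181374e+00 4.642351e+02 4.630186e+02
2.408746e+00 4.081735e+02 3.769782e-02 1.153797e+00 4.093650e+02 4.081736e+02
2.516985e+00 3.596639e+02 4.015015e-02 1.125226e+00 3.608293e+02 3.596641e+02
2.630087e+00 3.167771e+02 4.270116e-02 1.095713e+00 3.179155e+02 3.167773e+02
2.748272e+00 2.788782e+02 4.534739e-02 1.065318e+00 2.799888e+02 2.788784e+02
2.871767e+00 2.454021e+02 4.808434e-02 1.034106e+00 2.464843e+02 2.454024e+02
3.000812e+00 2.158461e+02 5.090638e-02 1.002150e+00 2.168992e+02 2.158464e+02
3.135655e+00 1.897631e+02 5.380713e-02 9.695389e-01 1.907865e+02 1.897635e+02
3.276558e+00 1.667587e+02 5.678044e-02 9.364086e-01 1.677519e+02 1.667590e+02
3.423792e+00 1.464812e+02 5.981975e-02 9.029010e-01 1.474439e+02 1.464816e+02
3.577643e+00 1.286173e+02 6.291767e-02 8.691538e-01 1.295494e+02 1.286178e+02
3.738406e+00 1.128884e+02 6.606605e-02 8.352989e-01 1.137897e+02 1.128889e+02
3.906394e+00 9.904640e+01 6.925597e-02 8.014622e-01 9.991712e+01 9.904692e+01
4.081931e+00 8.687100e+01 7.247781e-02 7.677639e-01 8.771125e+01 8.687157e+01
4.265355e+00 7.616571e+01 7.572104e-02 7.343422e-01 7.697577e+01 7.616633e+01
4.457021e+00 6.675578e+01 7.897409e-02 7.013503e-01 6.753611e+01 6.675646e+01
4.657301e+00 5.848688e+01 8.222478e-02 6.689251e-01 5.923803e+01 5.848761e+01
4.866579e+00 5.122282e+01 8.546029e-02 6.371862e-01 5.194547e+01 5.122362e+01
5.085262e+00 4.484355e+01 8.866713e-02 6.062360e-01 4.553845e+01 4.484441e+01
5.313772e+00 3.924369e+01 9.183377e-02 5.761541e-01 3.991168e+01 3.924462e+01
5.552550e+00 3.433070e+01 9.495218e-02 5.469971e-01 3.497265e+01 3.433171e+01
5.802057e+00 3.002267e+01 9.801481e-02 5.188097e-01 3.063949e+01 3.002375e+01
6.062777e+00 2.624707e+01 1.010146e-01 4.916269e-01 2.683971e+01 2.624824e+01
6.335212e+00 2.293961e+01 1.039453e-01 4.654777e-01 2.350903e+01 2.294086e+01
6.619889e+00 2.004307e+01 1.068013e-01 4.403888e-01 2.059026e+01 2.004441e+01
6.917358e+00 1.750716e+01 1.095779e-01 4.163777e-01 1.803311e+01 1.750860e+01
7.228194e+00 1.528764e+01 1.122711e-01 3.934523e-01 1.579336e+01 1.528918e+01
7.552997e+00 1.334563e+01 1.148773e-01 3.716121e-01 1.383212e+01 1.334727e+01
7.892396e+00 1.164693e+01 1.173941e-01 3.508490e-01 1.211517e+01 1.164868e+01
8.247046e+00 1.016145e+01 1.198196e-01 3.311479e-01 1.061241e+01 1.016331e+01
8.617633e+00 8.862819e+00 1.221551e-01 3.124801e-01 9.297454e+00 8.864806e+00
9.004872e+00 7.727867e+00 1.244038e-01 2.948098e-01 8.147080e+00 7.729977e+00
9.409512e+00 6.736234e+00 1.265701e-01 2.781002e-01 7.140905e+00 6.738474e+00
9.832334e+00 5.870066e+00 1.286593e-01 2.623135e-01 6.261039e+00 5.872441e+00
1.027416e+01 5.113721e+00 1.306769e-01 2.474109e-01 5.491809e+00 5.116238e+00
1.073583e+01 4.453492e+00 1.326265e-01 2.333428e-01 4.819461e+00 4.456155e+00
1.121825e+01 3.877369e+00 1.345095e-01 2.200549e-01 4.231933e+00 3.880186e+00
1.172235e+01 3.374820e+00 1.363275e-01 2.074968e-01 3.718645e+00 3.377798e+00
1.224911e+01 2.936604e+00 1.380828e-01 1.956224e-01 3.270310e+00 2.939749e+00
1.279953e+01 2.554617e+00 1.397777e-01 1.843892e-01 2.878784e+00 2.557936e+00
1.337468e+01 2.221753e+00 1.414151e-01 1.737581e-01 2.536926e+00 2.225253e+00
1.397568e+01 1.931789e+00 1.429981e-01 1.636930e-01 2.238480e+00 1.935479e+00
1.460369e+01 1.679274e+00 1.445302e-01 1.541607e-01 1.977965e+00 1.683161e+00
1.525992e+01 1.459438e+00 1.460150e-01 1.451306e-01 1.750583e+00 1.463530e+00
1.594563e+01 1.268099e+00 1.474536e-01 1.365719e-01 1.552124e+00 1.272405e+00
1.666216e+01 1.101600e+00 1.488432e-01 1.284538e-01 1.378897e+00 1.106130e+00
1.741088e+01 9.567481e-01 1.501805e-01 1.207483e-01 1.227677e+00 9.615097e-01
1.819325e+01 8.307548e-01 1.514626e-01 1.134303e-01 1.095648e+00 8.357573e-01
1.901078e+01 7.211883e-01 1.526863e-01 1.064772e-01 9.803518e-01 7.264409e-01
1.986504e+01 6.259278e-01 1.538485e-01 9.986873e-02 8.796450e-01 6.314396e-01
2.075769e+01 5.431317e-01 1.549463e-01 9.358782e-02 7.916659e-01 5.489120e-01
2.169045e+01 4.711827e-01 1.559773e-01 8.762312e-02 7.147832e-01 4.772408e-01
2.266512e+01 4.086767e-01 1.569393e-01 8.196561e-02 6.475817e-01 4.150220e-01
2.368360e+01 3.543897e-01 1.578303e-01 7.660600e-02 5.888260e-01 3.610315e-01
2.474783e+01 3.072536e-01 1.586482e-01 7.153467e-02 5.374365e-01 3.142014e-01
2.585989e+01 2.663373e-01 1.593912e-01 6.674175e-02 4.924703e-01 2.736003e-01
2.702193e+01 2.308290e-01 1.600574e-01 6.221717e-02 4.531035e-01 2.384163e-01
2.823617e+01 2.000213e-01 1.606451e-01 5.795077e-02 4.186171e-01 2.079421e-01
2.950498e+01 1.732981e-01 1.611527e-01 5.393230e-02 3.883831e-01 1.815613e-01
3.083081e+01 1.501177e-01 1.615787e-01 5.015072e-02 3.618472e-01 1.587321e-01
3.221621e+01 1.300168e-01 1.619225e-01 4.659755e-02 3.385368e-01 1.389909e-01
3.366387e+01 1.125920e-01 1.621839e-01 4.326487e-02 3.180408e-01 1.219343e-01
3.517658e+01 9.748968e-02 1.623628e-01 4.014381e-02 2.999963e-01 1.072082e-01
3.675726e+01 8.440229e-02 1.624594e-01 3.722520e-02 2.840869e-01 9.450494e-02
3.840897e+01 7.306283e-02 1.624740e-01 3.449967e-02 2.700365e-01 8.355721e-02
4.013491e+01 6.323971e-02 1.624070e-01 3.195788e-02 2.576046e-01 7.413308e-02
4.193839e+01 5.473489e-02 1.622594e-01 2.959115e-02 2.465854e-01 6.603419e-02
4.382292e+01 4.736856e-02 1.620333e-01 2.738796e-02 2.367898e-01 5.908044e-02
4.579214e+01 4.098913e-02 1.617312e-01 2.533837e-02 2.280587e-01 5.311998e-02
4.784984e+01 3.546509e-02 1.613560e-01 2.343291e-02 2.202540e-01 4.802098e-02
5.000000e+01 3.068233e-02 1.609102e-01 2.166253e-02 2.132551e-01 4.366904e-02
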