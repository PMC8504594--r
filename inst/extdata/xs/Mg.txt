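# Photon mass interaction coefficients for Mg (Z=12), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 9.202434e+02 1.543130e-02 2.145721e+00 9.224046e+02 9.202435e+02
1.044936e+00 8.180130e+02 1.634190e-02 2.126684e+00 8.201560e+02 8.180130e+02
1.091891e+00 7.271362e+02 1.730186e-02 2.107648e+00 7.292611e+02 7.271362e+02
1.140955e+00 6.463553e+02 1.830896e-02 2.088450e+00 6.484620e+02 6.463553e+02
1.192225e+00 5.737648e+02 1.936003e-02 2.068934e+00 5.758531e+02 5.737649e+02
1.245798e+00 5.093062e+02 2.045081e-02 2.048948e+00 5.113756e+02 5.093062e+02
1.301779e+00 4.520890e+02 2.157581e-02 2.028349e+00 4.541389e+02 4.520891e+02
1.304000e+00 5.432209e+03 2.162004e-02 2.027536e+00 5.434258e+03 5.432209e+03
1.306000e+00 5.414557e+03 2.165984e-02 2.026804e+00 5.416605e+03 5.414557e+03
1.360275e+00 4.964845e+03 2.272828e-02 2.006999e+00 4.966875e+03 4.964845e+03
1.421400e+00 4.514607e+03 2.390009e-02 1.984769e+00 4.516616e+03 4.514607e+03
1.485272e+00 4.092932e+03 2.508165e-02 1.961537e+00 4.094918e+03 4.092932e+03
1.552014e+00 3.694606e+03 2.626300e-02 1.937209e+00 3.696569e+03 3.694606e+03
1.621754e+00 3.320939e+03 2.744136e-02 1.911844e+00 3.322878e+03 3.320939e+03
1.694629e+00 2.974739e+03 2.861843e-02 1.885570e+00 2.976653e+03 2.974739e+03
1.770778e+00 2.657476e+03 2.979695e-02 1.858513e+00 2.659364e+03 2.657476e+03
1.850349e+00 2.369518e+03 3.098063e-02 1.830797e+00 2.371380e+03 2.369518e+03
1.933496e+00 2.110368e+03 3.217419e-02 1.802538e+00 2.112203e+03 2.110368e+03
2.020379e+00 1.878888e+03 3.338337e-02 1.773851e+00 1.880695e+03 1.878888e+03
2.111166e+00 1.673040e+03 3.461342e-02 1.744808e+00 1.674820e+03 1.673041e+03
2.206033e+00 1.489875e+03 3.586734e-02 1.715406e+00 1.491626e+03 1.489875e+03
2.305162e+00 1.326712e+03 3.714812e-02 1.685634e+00 1.328435e+03 1.326712e+03
2.408746e+00 1.181225e+03 3.845920e-02 1.655486e+00 1.182919e+03 1.181225e+03
2.516985e+00 1.051389e+03 3.980449e-02 1.624958e+00 1.053054e+03 1.051389e+03
2.630087e+00 9.354372e+02 4.118841e-02 1.594050e+00 9.370724e+02 9.354374e+02
2.748272e+00 8.318250e+02 4.261591e-02 1.562764e+00 8.334304e+02 8.318252e+02
2.871767e+00 7.391985e+02 4.409254e-02 1.531105e+00 7.407737e+02 7.391988e+02
3.000812e+00 6.563685e+02 4.562447e-02 1.499082e+00 6.579132e+02 6.563688e+02
3.135655e+00 5.823062e+02 4.721775e-02 1.466693e+00 5.838201e+02 5.823065e+02
3.276558e+00 5.161673e+02 4.887514e-02 1.433887e+00 5.176500e+02 5.161676e+02
3.423792e+00 4.571898e+02 5.059870e-02 1.400609e+00 4.586410e+02 4.571901e+02
3.577643e+00 4.046702e+02 5.239054e-02 1.366816e+00 4.060894e+02 4.046706e+02
3.738406e+00 3.579615e+02 5.425279e-02 1.332475e+00 3.593482e+02 3.579619e+02
3.906394e+00 3.164706e+02 5.618758e-02 1.297562e+00 3.178243e+02 3.164710e+02
4.081931e+00 2.796555e+02 5.819700e-02 1.262066e+00 2.809758e+02 2.796559e+02
4.265355e+00 2.470140e+02 6.028195e-02 1.225985e+00 2.483003e+02 2.470145e+02
4.457021e+00 2.180851e+02 6.244181e-02 1.189331e+00 2.193369e+02 2.180857e+02
4.657301e+00 1.924570e+02 6.467547e-02 1.152125e+00 1.936738e+02 1.924575e+02
4.866579e+00 1.697623e+02 6.698136e-02 1.114399e+00 1.709437e+02 1.697629e+02
5.085262e+00 1.496737e+02 6.935742e-02 1.076195e+00 1.508193e+02 1.496744e+02
5.313772e+00 1.319002e+02 7.180076e-02 1.037584e+00 1.330096e+02 1.319009e+02
5.552550e+00 1.161832e+02 7.430742e-02 9.986694e-01 1.172561e+02 1.161840e+02
5.802057e+00 1.022918e+02 7.687272e-02 9.595581e-01 1.033282e+02 1.022926e+02
6.062777e+00 9.002030e+01 7.949118e-02 9.203578e-01 9.102015e+01 9.002122e+01
6.335212e+00 7.918586e+01 8.215669e-02 8.811994e-01 8.014922e+01 7.918686e+01
6.619889e+00 6.962538e+01 8.486305e-02 8.422494e-01 7.055249e+01 6.962645e+01
6.917358e+00 6.119387e+01 8.760324e-02 8.036675e-01 6.208514e+01 6.119502e+01
7.228194e+00 5.376212e+01 9.036942e-02 7.655994e-01 5.461809e+01 5.376336e+01
7.552997e+00 4.721506e+01 9.315297e-02 7.281759e-01 4.803639e+01 4.721640e+01
7.892396e+00 4.145035e+01 9.594445e-02 6.915138e-01 4.223781e+01 4.145179e+01
8.247046e+00 3.637678e+01 9.873386e-02 6.557170e-01 3.713124e+01 3.637832e+01
8.617633e+00 3.191312e+01 1.015111e-01 6.209015e-01 3.263553e+01 3.191477e+01
9.004872e+00 2.798716e+01 1.042659e-01 5.871784e-01 2.867860e+01 2.798892e+01
9.409512e+00 2.453508e+01 1.069875e-01 5.546365e-01 2.519671e+01 2.453698e+01
9.832334e+00 2.150059e+01 1.096647e-01 5.233450e-01 2.213360e+01 2.150261e+01
1.027416e+01 1.883405e+01 1.122859e-01 4.933538e-01 1.943969e+01 1.883621e+01
1.073583e+01 1.649183e+01 1.148432e-01 4.646828e-01 1.707136e+01 1.649414e+01
1.121825e+01 1.443548e+01 1.173319e-01 4.373307e-01 1.499014e+01 1.443794e+01
1.172235e+01 1.263099e+01 1.197476e-01 4.112883e-01 1.316202e+01 1.263360e+01
1.224911e+01 1.104825e+01 1.220861e-01 3.865390e-01 1.155688e+01 1.105103e+01
1.279953e+01 9.660658e+00 1.243436e-01 3.630602e-01 1.014806e+01 9.663611e+00
1.337468e+01 8.444678e+00 1.265164e-01 3.408238e-01 8.912018e+00 8.447809e+00
1.397568e+01 7.379539e+00 1.286015e-01 3.197973e-01 7.827938e+00 7.382857e+00
1.460369e+01 6.446912e+00 1.305960e-01 2.999445e-01 6.877452e+00 6.450424e+00
1.525992e+01 5.630621e+00 1.324975e-01 2.812262e-01 6.044345e+00 5.634335e+00
1.594563e+01 4.916381e+00 1.343054e-01 2.635952e-01 5.314281e+00 4.920303e+00
1.666216e+01 4.291592e+00 1.360220e-01 2.469976e-01 4.674612e+00 4.295732e+00
1.741088e+01 3.745183e+00 1.376502e-01 2.313805e-01 4.114213e+00 3.749547e+00
1.819325e+01 3.267435e+00 1.391932e-01 2.166930e-01 3.623321e+00 3.272032e+00
1.901078e+01 2.849824e+00 1.406551e-01 2.028863e-01 3.193366e+00 2.854663e+00
1.986504e+01 2.484873e+00 1.420402e-01 1.899134e-01 2.816827e+00 2.489962e+00
2.075769e+01 2.166058e+00 1.433523e-01 1.777295e-01 2.487139e+00 2.171405e+00
2.169045e+01 1.887612e+00 1.445926e-01 1.662835e-01 2.198489e+00 1.893228e+00
2.266512e+01 1.644507e+00 1.457607e-01 1.555270e-01 1.945795e+00 1.650400e+00
2.368360e+01 1.432329e+00 1.468564e-01 1.454154e-01 1.724601e+00 1.438509e+00
2.474783e+01 1.247205e+00 1.478796e-01 1.359078e-01 1.530993e+00 1.253681e+00
2.585989e+01 1.085739e+00 1.488305e-01 1.269664e-01 1.361536e+00 1.092521e+00
2.702193e+01 9.449511e-01 1.497094e-01 1.185564e-01 1.213217e+00 9.520479e-01
2.823617e+01 8.222308e-01 1.505166e-01 1.106456e-01 1.083393e+00 8.296522e-01
2.950498e+01 7.152909e-01 1.512526e-01 1.032043e-01 9.697479e-01 7.230465e-01
3.083081e+01 6.221073e-01 1.519183e-01 9.620336e-02 8.702290e-01 6.302066e-01
3.221621e+01 5.409416e-01 1.525131e-01 8.961963e-02 7.830743e-01 5.493942e-01
3.366387e+01 4.702727e-01 1.530355e-01 8.343260e-02 7.067407e-01 4.790879e-01
3.517658e+01 4.087576e-01 1.534842e-01 7.762162e-02 6.398634e-01 4.179446e-01
3.675726e+01 3.552230e-01 1.538580e-01 7.216698e-02 5.812481e-01 3.647908e-01
3.840897e+01 3.086442e-01 1.541560e-01 6.704984e-02 5.298501e-01 3.186013e-01
4.013491e+01 2.681279e-01 1.543771e-01 6.225243e-02 4.847574e-01 2.784826e-01
4.193839e+01 2.329070e-01 1.545205e-01 5.776008e-02 4.451876e-01 2.436674e-01
4.382292e+01 2.022780e-01 1.545859e-01 5.355658e-02 4.104205e-01 2.134516e-01
4.579214e+01 1.756465e-01 1.545732e-01 4.962843e-02 3.798481e-01 1.872405e-01
4.784984e+01 1.524944e-01 1.544824e-01 4.596212e-02 3.529389e-01 1.645155e-01
5.000000e+01 1.323706e-01 1.543135e-01 4.254420e-02 3.292282e-01 1.448249e-01
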