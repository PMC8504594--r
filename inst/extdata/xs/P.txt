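# Photon mass interaction coefficients for P (Z=15), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 1.910077e+03 1.112692e-02 2.655876e+00 1.912744e+03 1.910076e+03
1.044936e+00 1.700080e+03 1.193951e-02 2.632393e+00 1.702724e+03 1.700079e+03
1.091891e+00 1.513165e+03 1.280903e-02 2.608833e+00 1.515786e+03 1.513164e+03
1.140955e+00 1.346800e+03 1.373667e-02 2.584922e+00 1.349399e+03 1.346799e+03
1.192225e+00 1.198726e+03 1.472315e-02 2.560396e+00 1.201301e+03 1.198726e+03
1.245798e+00 1.066932e+03 1.576855e-02 2.535001e+00 1.069483e+03 1.066932e+03
1.301779e+00 9.496285e+02 1.687223e-02 2.508496e+00 9.521539e+02 9.496282e+02
1.360275e+00 8.452217e+02 1.803271e-02 2.480650e+00 8.477204e+02 8.452214e+02
1.421400e+00 7.522939e+02 1.924753e-02 2.451249e+00 7.547644e+02 7.522936e+02
1.485272e+00 6.695830e+02 2.051316e-02 2.420093e+00 6.720236e+02 6.695828e+02
1.552014e+00 5.948558e+02 2.182528e-02 2.387022e+00 5.972647e+02 5.948557e+02
1.621754e+00 5.281834e+02 2.318200e-02 2.352079e+00 5.305587e+02 5.281833e+02
1.694629e+00 4.689837e+02 2.458287e-02 2.315402e+00 4.713237e+02 4.689836e+02
1.770778e+00 4.164192e+02 2.602746e-02 2.277130e+00 4.187224e+02 4.164192e+02
1.850349e+00 3.697463e+02 2.751536e-02 2.237402e+00 3.720112e+02 3.697462e+02
1.933496e+00 3.283045e+02 2.904623e-02 2.196358e+00 3.305299e+02 3.283045e+02
2.020379e+00 2.914274e+02 3.061978e-02 2.154135e+00 2.936121e+02 2.914274e+02
2.111166e+00 2.584553e+02 3.223526e-02 2.110876e+00 2.605984e+02 2.584553e+02
2.144500e+00 2.476284e+02 3.282082e-02 2.095235e+00 2.497564e+02 2.476285e+02
2.146500e+00 2.468543e+03 3.285582e-02 2.094301e+00 2.470670e+03 2.334973e+03
2.206033e+00 2.318019e+03 3.389080e-02 2.066726e+00 2.320119e+03 2.195978e+03
2.305162e+00 2.094732e+03 3.558415e-02 2.021832e+00 2.096789e+03 1.989190e+03
2.408746e+00 1.891953e+03 3.731282e-02 1.976334e+00 1.893967e+03 1.800727e+03
2.516985e+00 1.707347e+03 3.907407e-02 1.930366e+00 1.709317e+03 1.628563e+03
2.630087e+00 1.538943e+03 4.086495e-02 1.884059e+00 1.540867e+03 1.470983e+03
2.748272e+00 1.385068e+03 4.268228e-02 1.837537e+00 1.386949e+03 1.326534e+03
2.871767e+00 1.244308e+03 4.452264e-02 1.790917e+00 1.246143e+03 1.193983e+03
3.000812e+00 1.115453e+03 4.638244e-02 1.744310e+00 1.117244e+03 1.072280e+03
3.135655e+00 9.975895e+02 4.825823e-02 1.697827e+00 9.993356e+02 9.606390e+02
3.276558e+00 8.903081e+02 5.014779e-02 1.651592e+00 8.920098e+02 8.587494e+02
3.423792e+00 7.931883e+02 5.204936e-02 1.605725e+00 7.948461e+02 7.662814e+02
3.577643e+00 7.056989e+02 5.396135e-02 1.560335e+00 7.073132e+02 6.827894e+02
3.738406e+00 6.272339e+02 5.588236e-02 1.515522e+00 6.288053e+02 6.077474e+02
3.906394e+00 5.571423e+02 5.781117e-02 1.471376e+00 5.586715e+02 5.405777e+02
4.081931e+00 4.947494e+02 5.974682e-02 1.427975e+00 4.962371e+02 4.806725e+02
4.265355e+00 4.392806e+02 6.168924e-02 1.385337e+00 4.407276e+02 4.273196e+02
4.457021e+00 3.899239e+02 6.363942e-02 1.343422e+00 3.913310e+02 3.797635e+02
4.657301e+00 3.459684e+02 6.559884e-02 1.302189e+00 3.473362e+02 3.373411e+02
4.866579e+00 3.067958e+02 6.756944e-02 1.261604e+00 3.081250e+02 2.994745e+02
5.085262e+00 2.718675e+02 6.955356e-02 1.221639e+00 2.731587e+02 2.656589e+02
5.313772e+00 2.407348e+02 7.155374e-02 1.182243e+00 2.419886e+02 2.354737e+02
5.552550e+00 2.130227e+02 7.357267e-02 1.143341e+00 2.142396e+02 2.085676e+02
5.802057e+00 1.883886e+02 7.561335e-02 1.104868e+00 1.895691e+02 1.846183e+02
6.062777e+00 1.665182e+02 7.767920e-02 1.066771e+00 1.676626e+02 1.633291e+02
6.335212e+00 1.471205e+02 7.977275e-02 1.029006e+00 1.482292e+02 1.444242e+02
6.619889e+00 1.299244e+02 8.189399e-02 9.915302e-01 1.309979e+02 1.276460e+02
6.917358e+00 1.146874e+02 8.404259e-02 9.543163e-01 1.157258e+02 1.127629e+02
7.228194e+00 1.011926e+02 8.621824e-02 9.173463e-01 1.021961e+02 9.956774e+01
7.552997e+00 8.924626e+01 8.842063e-02 8.806134e-01 9.021530e+01 8.787516e+01
7.892396e+00 7.867577e+01 9.064942e-02 8.441207e-01 7.961054e+01 7.751932e+01
8.247046e+00 6.932661e+01 9.290423e-02 8.078839e-01 7.022740e+01 6.835171e+01
8.617633e+00 6.106158e+01 9.518180e-02 7.719658e-01 6.192873e+01 6.024016e+01
9.004872e+00 5.375831e+01 9.747701e-02 7.364513e-01 5.459224e+01 5.306659e+01
9.409512e+00 4.730774e+01 9.978439e-02 7.014213e-01 4.810894e+01 4.672557e+01
9.832334e+00 4.161281e+01 1.020980e-01 6.669524e-01 4.238186e+01 4.112314e+01
1.027416e+01 3.658736e+01 1.044113e-01 6.331203e-01 3.732490e+01 3.617577e+01
1.073583e+01 3.215491e+01 1.067180e-01 6.000346e-01 3.286166e+01 3.180919e+01
1.121825e+01 2.824754e+01 1.090116e-01 5.678185e-01 2.892437e+01 2.795737e+01
1.172235e+01 2.480490e+01 1.112851e-01 5.365761e-01 2.545276e+01 2.456156e+01
1.224911e+01 2.177326e+01 1.135312e-01 5.063921e-01 2.239318e+01 2.156939e+01
1.279953e+01 1.910490e+01 1.157423e-01 4.773332e-01 1.969798e+01 1.893429e+01
1.337468e+01 1.675744e+01 1.179106e-01 4.494494e-01 1.732480e+01 1.661483e+01
1.397568e+01 1.469324e+01 1.200276e-01 4.227754e-01 1.523605e+01 1.457423e+01
1.460369e+01 1.287897e+01 1.220850e-01 3.973322e-01 1.339839e+01 1.277983e+01
1.525992e+01 1.128506e+01 1.240741e-01 3.731280e-01 1.178226e+01 1.120264e+01
1.594563e+01 9.885259e+00 1.259890e-01 3.501552e-01 1.036140e+01 9.816936e+00
1.666216e+01 8.656326e+00 1.278270e-01 3.283909e-01 9.112544e+00 8.599877e+00
1.741088e+01 7.577730e+00 1.295863e-01 3.078069e-01 8.015123e+00 7.531289e+00
1.819325e+01 6.631370e+00 1.312652e-01 2.883706e-01 7.051006e+00 6.593371e+00
1.901078e+01 5.801292e+00 1.328623e-01 2.700460e-01 6.204200e+00 5.770420e+00
1.986504e+01 5.073435e+00 1.343765e-01 2.527943e-01 5.460606e+00 5.048586e+00
2.075769e+01 4.435479e+00 1.358068e-01 2.365743e-01 4.807860e+00 4.415728e+00
2.169045e+01 3.876481e+00 1.371537e-01 2.213308e-01 4.234966e+00 3.861051e+00
2.266512e+01 3.386853e+00 1.384180e-01 2.070080e-01 3.732279e+00 3.375093e+00
2.368360e+01 2.958149e+00 1.396008e-01 1.935534e-01 3.291303e+00 2.949517e+00
2.474783e+01 2.582931e+00 1.407035e-01 1.809172e-01 2.904552e+00 2.576971e+00
2.585989e+01 2.254646e+00 1.417276e-01 1.690527e-01 2.565427e+00 2.250978e+00
2.702193e+01 1.967526e+00 1.426750e-01 1.579153e-01 2.268116e+00 1.965833e+00
2.823617e+01 1.716497e+00 1.435478e-01 1.474633e-01 2.007508e+00 1.716514e+00
2.950498e+01 1.497095e+00 1.443484e-01 1.376571e-01 1.779101e+00 1.498604e+00
3.083081e+01 1.305357e+00 1.450792e-01 1.284569e-01 1.578893e+00 1.308174e+00
3.221621e+01 1.137873e+00 1.457410e-01 1.198258e-01 1.403440e+00 1.141848e+00
3.366387e+01 9.916516e-01 1.463332e-01 1.117282e-01 1.249713e+00 9.966594e-01
3.517658e+01 8.640370e-01 1.468553e-01 1.041297e-01 1.115022e+00 8.699744e-01
3.675726e+01 7.526975e-01 1.473072e-01 9.699888e-02 9.970036e-01 7.594796e-01
3.840897e+01 6.555876e-01 1.476887e-01 9.030656e-02 8.935829e-01 6.631445e-01
4.013491e+01 5.709165e-01 1.479998e-01 8.402608e-02 8.029423e-01 5.791913e-01
4.193839e+01 4.971376e-01 1.482401e-01 7.813584e-02 7.235136e-01 5.060839e-01
4.382292e+01 4.328170e-01 1.484092e-01 7.261248e-02 6.538386e-01 4.423970e-01
4.579214e+01 3.767422e-01 1.485065e-01 6.743712e-02 5.926858e-01 3.869255e-01
4.784984e+01 3.278576e-01 1.485315e-01 6.259149e-02 5.389806e-01 3.386198e-01
5.000000e+01 2.852438e-01 1.484838e-01 5.805800e-02 4.917855e-01 2.965650e-01
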