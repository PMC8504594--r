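# Photon mass interaction coefficients for Al (Z=13), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 1.182944e+03 1.427098e-02 2.256500e+00 1.185215e+03 1.182944e+03
1.044936e+00 1.051810e+03 1.519879e-02 2.234793e+00 1.054060e+03 1.051809e+03
1.091891e+00 9.352108e+02 1.618322e-02 2.213094e+00 9.374401e+02 9.352107e+02
1.140955e+00 8.315377e+02 1.722357e-02 2.191209e+00 8.337462e+02 8.315376e+02
1.192225e+00 7.393574e+02 1.831828e-02 2.168952e+00 7.415446e+02 7.393572e+02
1.245798e+00 6.573957e+02 1.946484e-02 2.146144e+00 6.595613e+02 6.573956e+02
1.301779e+00 5.845199e+02 2.065963e-02 2.122616e+00 5.866631e+02 5.845198e+02
1.360275e+00 5.197227e+02 2.189783e-02 2.098206e+00 5.218428e+02 5.197227e+02
1.421400e+00 4.621087e+02 2.317327e-02 2.072764e+00 4.642046e+02 4.621087e+02
1.485272e+00 4.108815e+02 2.447837e-02 2.046149e+00 4.129521e+02 4.108815e+02
1.552014e+00 3.644744e+02 2.580473e-02 2.018253e+00 3.665185e+02 3.644744e+02
1.558600e+00 3.602665e+02 2.593344e-02 2.015499e+00 3.623079e+02 3.602665e+02
1.560600e+00 3.946200e+03 2.597245e-02 2.014663e+00 3.948241e+03 3.813910e+03
1.621754e+00 3.629334e+03 2.714815e-02 1.989146e+00 3.631350e+03 3.512254e+03
1.694629e+00 3.296403e+03 2.850696e-02 1.958978e+00 3.298390e+03 3.194636e+03
1.770778e+00 2.990795e+03 2.987980e-02 1.927898e+00 2.992753e+03 2.902434e+03
1.850349e+00 2.709069e+03 3.126559e-02 1.896048e+00 2.710997e+03 2.632473e+03
1.933496e+00 2.448469e+03 3.266358e-02 1.863566e+00 2.450365e+03 2.382218e+03
2.020379e+00 2.206809e+03 3.407339e-02 1.830586e+00 2.208674e+03 2.149665e+03
2.111166e+00 1.982931e+03 3.549478e-02 1.797212e+00 1.984764e+03 1.933792e+03
2.206033e+00 1.776836e+03 3.692757e-02 1.763504e+00 1.778637e+03 1.734698e+03
2.305162e+00 1.588326e+03 3.837182e-02 1.729513e+00 1.590094e+03 1.552279e+03
2.408746e+00 1.416903e+03 3.982791e-02 1.695292e+00 1.418638e+03 1.386129e+03
2.516985e+00 1.261839e+03 4.129663e-02 1.660890e+00 1.263541e+03 1.235611e+03
2.630087e+00 1.122242e+03 4.277911e-02 1.626355e+00 1.123911e+03 1.099919e+03
2.748272e+00 9.971118e+02 4.427690e-02 1.591736e+00 9.987478e+02 9.781308e+02
2.871767e+00 8.853827e+02 4.579196e-02 1.557077e+00 8.869856e+02 8.692534e+02
3.000812e+00 7.859658e+02 4.732669e-02 1.522423e+00 7.875356e+02 7.722634e+02
3.135655e+00 6.977189e+02 4.888400e-02 1.487803e+00 6.992555e+02 6.860781e+02
3.276558e+00 6.193527e+02 5.046721e-02 1.453190e+00 6.208564e+02 6.094639e+02
3.423792e+00 5.496898e+02 5.208018e-02 1.418553e+00 5.511604e+02 5.412907e+02
3.577643e+00 4.877087e+02 5.372733e-02 1.383862e+00 4.891462e+02 4.805771e+02
3.738406e+00 4.325214e+02 5.541359e-02 1.349097e+00 4.339260e+02 4.264690e+02
3.906394e+00 3.833544e+02 5.714452e-02 1.314242e+00 3.847257e+02 3.782207e+02
4.081931e+00 3.395323e+02 5.892614e-02 1.279284e+00 3.408705e+02 3.351811e+02
4.265355e+00 3.004923e+02 6.076241e-02 1.244192e+00 3.017973e+02 2.968071e+02
4.457021e+00 2.657583e+02 6.265449e-02 1.208916e+00 2.670299e+02 2.626394e+02
4.657301e+00 2.348947e+02 6.460334e-02 1.173415e+00 2.361327e+02 2.322566e+02
4.866579e+00 2.075027e+02 6.660989e-02 1.137660e+00 2.087070e+02 2.052726e+02
5.085262e+00 1.832188e+02 6.867503e-02 1.101633e+00 1.843891e+02 1.813345e+02
5.313772e+00 1.617071e+02 7.079871e-02 1.065334e+00 1.628432e+02 1.601157e+02
5.552550e+00 1.426593e+02 7.297949e-02 1.028773e+00 1.437610e+02 1.413159e+02
5.802057e+00 1.257998e+02 7.521552e-02 9.919751e-01 1.268670e+02 1.246663e+02
6.062777e+00 1.108835e+02 7.750457e-02 9.549726e-01 1.119160e+02 1.099276e+02
6.335212e+00 9.769246e+01 7.984370e-02 9.178314e-01 9.869014e+01 9.688667e+01
6.619889e+00 8.603213e+01 8.222913e-02 8.806637e-01 8.699502e+01 8.535325e+01
6.917358e+00 7.572979e+01 8.465635e-02 8.435852e-01 7.665803e+01 7.515815e+01
7.228194e+00 6.663160e+01 8.712033e-02 8.067074e-01 6.752543e+01 6.615052e+01
7.552997e+00 5.860059e+01 8.961544e-02 7.701367e-01 5.946034e+01 5.819597e+01
7.892396e+00 5.151490e+01 9.213543e-02 7.339741e-01 5.234101e+01 5.117479e+01
8.247046e+00 4.526598e+01 9.467351e-02 6.983181e-01 4.605897e+01 4.498030e+01
8.617633e+00 3.975822e+01 9.722159e-02 6.633037e-01 4.051874e+01 3.951843e+01
9.004872e+00 3.490668e+01 9.977063e-02 6.290738e-01 3.563552e+01 3.470557e+01
9.409512e+00 3.063559e+01 1.023109e-01 5.957503e-01 3.133366e+01 3.046707e+01
9.832334e+00 2.687757e+01 1.048319e-01 5.634349e-01 2.754583e+01 2.673649e+01
1.027416e+01 2.357276e+01 1.073227e-01 5.322111e-01 2.421229e+01 2.345479e+01
1.073583e+01 2.066761e+01 1.097749e-01 5.021406e-01 2.127953e+01 2.056910e+01
1.121825e+01 1.811457e+01 1.121823e-01 4.732674e-01 1.870002e+01 1.803245e+01
1.172235e+01 1.587168e+01 1.145386e-01 4.456219e-01 1.643184e+01 1.580334e+01
1.224911e+01 1.390188e+01 1.168373e-01 4.192222e-01 1.443794e+01 1.384517e+01
1.279953e+01 1.217249e+01 1.190721e-01 3.940747e-01 1.268564e+01 1.212557e+01
1.337468e+01 1.065467e+01 1.212365e-01 3.701761e-01 1.114608e+01 1.061599e+01
1.397568e+01 9.322957e+00 1.233242e-01 3.475142e-01 9.793795e+00 9.291239e+00
1.460369e+01 8.154927e+00 1.253288e-01 3.260694e-01 8.606325e+00 8.129083e+00
1.525992e+01 7.130790e+00 1.272441e-01 3.058154e-01 7.563850e+00 7.109910e+00
1.594563e+01 6.233149e+00 1.290671e-01 2.867125e-01 6.648928e+00 6.216468e+00
1.666216e+01 5.446715e+00 1.307994e-01 2.687093e-01 5.846224e+00 5.433594e+00
1.741088e+01 4.757990e+00 1.324435e-01 2.517540e-01 5.142188e+00 4.747893e+00
1.819325e+01 4.155072e+00 1.340020e-01 2.357962e-01 4.524871e+00 4.147550e+00
1.901078e+01 3.627473e+00 1.354785e-01 2.207869e-01 3.983738e+00 3.622151e+00
1.986504e+01 3.165954e+00 1.368768e-01 2.066782e-01 3.509509e+00 3.162520e+00
2.075769e+01 2.762423e+00 1.382006e-01 1.934242e-01 3.094048e+00 2.760616e+00
2.169045e+01 2.409675e+00 1.394510e-01 1.809724e-01 2.730098e+00 2.409279e+00
2.266512e+01 2.101407e+00 1.406280e-01 1.692725e-01 2.411307e+00 2.102242e+00
2.368360e+01 1.832092e+00 1.417317e-01 1.582779e-01 2.132102e+00 1.834010e+00
2.474783e+01 1.596879e+00 1.427627e-01 1.479455e-01 1.887587e+00 1.599755e+00
2.585989e+01 1.391508e+00 1.437214e-01 1.382351e-01 1.673465e+00 1.395242e+00
2.702193e+01 1.212246e+00 1.446087e-01 1.291092e-01 1.485964e+00 1.216754e+00
2.823617e+01 1.055818e+00 1.454254e-01 1.205330e-01 1.321776e+00 1.061032e+00
2.950498e+01 9.193527e-01 1.461727e-01 1.124740e-01 1.177999e+00 9.252177e-01
3.083081e+01 8.003083e-01 1.468518e-01 1.049001e-01 1.052060e+00 8.067794e-01
3.221621e+01 6.965031e-01 1.474624e-01 9.778366e-02 9.417492e-01 7.035448e-01
3.366387e+01 6.060275e-01 1.480032e-01 9.109887e-02 8.451295e-01 6.136110e-01
3.517658e+01 5.271916e-01 1.484730e-01 8.482060e-02 7.604852e-01 5.352947e-01
3.675726e+01 4.585168e-01 1.488708e-01 7.892537e-02 6.863129e-01 4.671218e-01
3.840897e+01 3.987091e-01 1.491955e-01 7.339123e-02 6.212958e-01 4.078027e-01
4.013491e+01 3.466389e-01 1.494463e-01 6.819781e-02 5.642830e-01 3.562110e-01
4.193839e+01 3.013351e-01 1.496223e-01 6.332877e-02 5.142861e-01 3.113784e-01
4.382292e+01 2.619054e-01 1.497239e-01 5.876686e-02 4.703962e-01 2.724149e-01
4.579214e+01 2.275952e-01 1.497513e-01 5.449800e-02 4.318445e-01 2.385675e-01
4.784984e+01 1.977456e-01 1.497049e-01 5.050810e-02 3.979586e-01 2.091787e-01
5.000000e+01 1.717818e-01 1.495851e-01 4.678316e-02 3.681501e-01 1.836747e-01
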