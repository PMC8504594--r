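# Photon mass interaction coefficients for S (Z=16), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 2.426898e+03 1.011133e-02 2.947215e+00 2.429855e+03 2.426898e+03
1.044936e+00 2.160860e+03 1.088478e-02 2.923269e+00 2.163794e+03 2.160860e+03
1.091891e+00 1.923979e+03 1.171537e-02 2.899202e+00 1.926890e+03 1.923979e+03
1.140955e+00 1.713065e+03 1.260499e-02 2.874710e+00 1.715953e+03 1.713065e+03
1.192225e+00 1.525273e+03 1.355513e-02 2.849497e+00 1.528136e+03 1.525273e+03
1.245798e+00 1.358067e+03 1.456684e-02 2.823281e+00 1.360905e+03 1.358067e+03
1.301779e+00 1.209191e+03 1.564056e-02 2.795789e+00 1.212002e+03 1.209191e+03
1.360275e+00 1.076635e+03 1.677603e-02 2.766764e+00 1.079419e+03 1.076635e+03
1.421400e+00 9.586106e+02 1.797221e-02 2.735963e+00 9.613646e+02 9.586107e+02
1.485272e+00 8.535243e+02 1.922712e-02 2.703159e+00 8.562467e+02 8.535244e+02
1.552014e+00 7.585344e+02 2.053803e-02 2.668165e+00 7.612231e+02 7.585344e+02
1.621754e+00 6.737502e+02 2.190397e-02 2.630988e+00 6.764031e+02 6.737502e+02
1.694629e+00 5.984426e+02 2.332492e-02 2.591728e+00 6.010577e+02 5.984427e+02
1.770778e+00 5.315525e+02 2.480075e-02 2.550489e+00 5.341278e+02 5.315526e+02
1.850349e+00 4.721389e+02 2.633119e-02 2.507382e+00 4.746727e+02 4.721390e+02
1.933496e+00 4.193662e+02 2.791587e-02 2.462520e+00 4.218567e+02 4.193663e+02
2.020379e+00 3.723679e+02 2.955430e-02 2.416020e+00 3.748135e+02 3.723680e+02
2.111166e+00 3.302691e+02 3.124555e-02 2.368018e+00 3.326683e+02 3.302692e+02
2.206033e+00 2.929298e+02 3.298789e-02 2.318679e+00 2.952815e+02 2.929299e+02
2.305162e+00 2.598120e+02 3.477914e-02 2.268170e+00 2.621149e+02 2.598121e+02
2.408746e+00 2.304384e+02 3.661682e-02 2.216655e+00 2.326917e+02 2.304386e+02
2.471000e+00 2.149352e+02 3.770380e-02 2.186352e+00 2.171593e+02 2.149354e+02
2.473000e+00 2.066273e+03 3.773850e-02 2.185386e+00 2.068496e+03 1.927403e+03
2.516985e+00 1.988305e+03 3.849807e-02 2.164294e+00 1.990507e+03 1.857010e+03
2.630087e+00 1.805719e+03 4.041971e-02 2.111244e+00 1.807871e+03 1.691609e+03
2.748272e+00 1.637616e+03 4.237821e-02 2.057656e+00 1.639716e+03 1.538579e+03
2.871767e+00 1.481628e+03 4.436969e-02 2.003676e+00 1.483676e+03 1.395878e+03
3.000812e+00 1.335988e+03 4.638994e-02 1.949444e+00 1.337984e+03 1.261993e+03
3.135655e+00 1.199774e+03 4.843474e-02 1.895107e+00 1.201718e+03 1.136181e+03
3.276558e+00 1.073570e+03 5.050024e-02 1.840859e+00 1.075461e+03 1.019113e+03
3.423792e+00 9.578943e+02 5.258279e-02 1.786889e+00 9.597338e+02 9.113945e+02
3.577643e+00 8.528718e+02 5.467867e-02 1.733373e+00 8.546599e+02 8.132507e+02
3.738406e+00 7.583178e+02 5.678410e-02 1.680468e+00 7.600551e+02 7.246043e+02
3.906394e+00 6.738179e+02 5.889527e-02 1.628318e+00 6.755051e+02 6.451495e+02
4.081931e+00 5.987872e+02 6.100837e-02 1.577049e+00 6.004252e+02 5.744067e+02
4.265355e+00 5.322949e+02 6.312079e-02 1.526746e+00 5.338847e+02 5.115538e+02
4.457021e+00 4.732252e+02 6.523151e-02 1.477453e+00 4.747679e+02 4.555789e+02
4.657301e+00 4.206233e+02 6.733992e-02 1.429208e+00 4.221199e+02 4.056131e+02
4.866579e+00 3.736824e+02 6.944582e-02 1.382043e+00 3.751339e+02 3.609209e+02
5.085262e+00 3.317201e+02 7.154947e-02 1.335982e+00 3.331276e+02 3.208790e+02
5.313772e+00 2.942048e+02 7.365199e-02 1.291004e+00 2.955695e+02 2.850034e+02
5.552550e+00 2.607253e+02 7.575546e-02 1.247032e+00 2.620481e+02 2.529218e+02
5.802057e+00 2.309014e+02 7.786266e-02 1.203995e+00 2.321832e+02 2.242878e+02
6.062777e+00 2.043779e+02 7.997688e-02 1.161831e+00 2.056197e+02 1.987760e+02
6.335212e+00 1.808187e+02 8.210089e-02 1.120469e+00 1.820212e+02 1.760759e+02
6.619889e+00 1.599025e+02 8.423614e-02 1.079814e+00 1.610666e+02 1.558889e+02
6.917358e+00 1.413408e+02 8.638394e-02 1.039782e+00 1.424670e+02 1.379459e+02
7.228194e+00 1.248758e+02 8.854586e-02 1.000304e+00 1.259646e+02 1.220056e+02
7.552997e+00 1.102769e+02 9.072375e-02 9.613254e-01 1.113289e+02 1.078515e+02
7.892396e+00 9.733846e+01 9.291974e-02 9.228047e-01 9.835418e+01 9.529001e+01
8.247046e+00 8.587643e+01 9.513599e-02 8.847130e-01 8.685628e+01 8.414722e+01
8.617633e+00 7.572793e+01 9.737154e-02 8.470491e-01 7.667235e+01 7.426897e+01
9.004872e+00 6.674761e+01 9.962337e-02 8.098282e-01 6.765706e+01 6.551732e+01
9.409512e+00 5.880538e+01 1.018882e-01 7.730717e-01 5.968034e+01 5.776847e+01
9.832334e+00 5.178503e+01 1.041627e-01 7.368067e-01 5.262600e+01 5.091159e+01
1.027416e+01 4.558301e+01 1.064430e-01 7.010708e-01 4.639053e+01 4.484767e+01
1.073583e+01 4.010670e+01 1.087243e-01 6.659625e-01 4.088139e+01 3.948798e+01
1.121825e+01 3.527354e+01 1.110004e-01 6.316120e-01 3.601615e+01 3.475327e+01
1.172235e+01 3.101013e+01 1.132651e-01 5.981332e-01 3.172153e+01 3.057293e+01
1.224911e+01 2.725114e+01 1.155115e-01 5.656222e-01 2.793228e+01 2.688401e+01
1.279953e+01 2.393847e+01 1.177327e-01 5.341585e-01 2.459037e+01 2.363042e+01
1.337468e+01 2.102050e+01 1.199212e-01 5.038057e-01 2.164423e+01 2.076225e+01
1.397568e+01 1.845136e+01 1.220692e-01 4.746127e-01 1.904805e+01 1.823508e+01
1.460369e+01 1.619038e+01 1.241689e-01 4.466148e-01 1.676116e+01 1.600946e+01
1.525992e+01 1.420143e+01 1.262118e-01 4.198347e-01 1.474748e+01 1.405029e+01
1.594563e+01 1.245248e+01 1.281913e-01 3.942879e-01 1.297496e+01 1.232643e+01
1.666216e+01 1.091514e+01 1.301032e-01 3.699836e-01 1.141523e+01 1.081022e+01
1.741088e+01 9.564295e+00 1.319435e-01 3.469205e-01 1.004316e+01 9.477177e+00
1.819325e+01 8.377740e+00 1.337082e-01 3.250874e-01 8.836536e+00 8.305621e+00
1.901078e+01 7.335864e+00 1.353935e-01 3.044649e-01 7.775722e+00 7.276386e+00
1.986504e+01 6.421347e+00 1.369958e-01 2.850269e-01 6.843370e+00 6.372530e+00
2.075769e+01 5.618990e+00 1.385118e-01 2.667404e-01 6.024242e+00 5.579167e+00
2.169045e+01 4.915254e+00 1.399410e-01 2.495490e-01 5.304744e+00 4.883026e+00
2.266512e+01 4.298259e+00 1.412838e-01 2.333928e-01 4.672936e+00 4.272452e+00
2.368360e+01 3.757531e+00 1.425414e-01 2.182151e-01 4.118288e+00 3.737160e+00
2.474783e+01 3.283827e+00 1.437147e-01 2.039620e-01 3.631504e+00 3.268067e+00
2.585989e+01 2.868998e+00 1.448054e-01 1.905818e-01 3.204385e+00 2.857157e+00
2.702193e+01 2.505860e+00 1.458151e-01 1.780258e-01 2.829701e+00 2.497359e+00
2.823617e+01 2.188086e+00 1.467458e-01 1.662473e-01 2.501079e+00 2.182442e+00
2.950498e+01 1.910106e+00 1.475997e-01 1.552022e-01 2.212908e+00 1.906915e+00
3.083081e+01 1.666962e+00 1.483794e-01 1.448455e-01 1.960187e+00 1.665886e+00
3.221621e+01 1.454378e+00 1.490856e-01 1.351354e-01 1.738599e+00 1.455138e+00
3.366387e+01 1.268595e+00 1.497182e-01 1.260312e-01 1.544345e+00 1.270956e+00
3.517658e+01 1.106278e+00 1.502773e-01 1.174934e-01 1.374049e+00 1.110046e+00
3.675726e+01 9.645000e-01 1.507631e-01 1.094860e-01 1.224749e+00 9.695141e-01
3.840897e+01 8.406954e-01 1.511759e-01 1.019754e-01 1.093847e+00 8.468221e-01
4.013491e+01 7.326178e-01 1.515161e-01 9.493087e-02 9.790647e-01 7.397467e-01
4.193839e+01 6.383325e-01 1.517839e-01 8.832719e-02 8.784436e-01 6.463725e-01
4.382292e+01 5.560551e-01 1.519794e-01 8.213536e-02 7.901699e-01 5.649314e-01
4.579214e+01 4.842731e-01 1.521025e-01 7.633190e-02 7.127075e-01 4.939240e-01
4.784984e+01 4.216621e-01 1.521532e-01 7.089467e-02 6.447099e-01 4.320372e-01
5.000000e+01 3.670631e-01 1.521315e-01 6.580279e-02 5.849974e-01 3.781212e-01
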