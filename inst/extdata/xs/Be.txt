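# Photon mass interaction coefficients for Be (Z=4), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 6.035473e+02 2.090853e-02 5.918448e-01 6.041600e+02 6.035473e+02
1.044936e+00 5.294792e+02 2.237837e-02 5.818314e-01 5.300834e+02 5.294792e+02
1.091891e+00 4.644764e+02 2.394572e-02 5.718907e-01 4.650722e+02 4.644764e+02
1.140955e+00 4.074108e+02 2.561043e-02 5.619305e-01 4.079983e+02 4.074108e+02
1.192225e+00 3.572996e+02 2.737098e-02 5.518647e-01 3.578788e+02 3.572997e+02
1.245798e+00 3.132859e+02 2.922423e-02 5.416142e-01 3.138567e+02 3.132859e+02
1.301779e+00 2.746213e+02 3.116519e-02 5.311065e-01 2.751836e+02 2.746214e+02
1.360275e+00 2.406523e+02 3.318679e-02 5.202765e-01 2.412058e+02 2.406524e+02
1.421400e+00 2.108071e+02 3.527966e-02 5.090666e-01 2.113515e+02 2.108072e+02
1.485272e+00 1.845852e+02 3.743191e-02 4.974274e-01 1.851201e+02 1.845853e+02
1.552014e+00 1.615491e+02 3.962979e-02 4.853279e-01 1.620741e+02 1.615492e+02
1.621754e+00 1.413216e+02 4.186452e-02 4.728230e-01 1.418362e+02 1.413217e+02
1.694629e+00 1.235715e+02 4.413007e-02 4.600036e-01 1.240757e+02 1.235717e+02
1.770778e+00 1.080052e+02 4.642015e-02 4.469562e-01 1.084986e+02 1.080053e+02
1.850349e+00 9.436196e+01 4.872831e-02 4.337622e-01 9.484445e+01 9.436214e+01
1.933496e+00 8.241108e+01 5.104797e-02 4.204972e-01 8.288262e+01 8.241127e+01
2.020379e+00 7.194832e+01 5.337247e-02 4.072314e-01 7.240892e+01 7.194853e+01
2.111166e+00 6.279278e+01 5.569531e-02 3.940276e-01 6.324250e+01 6.279301e+01
2.206033e+00 5.478394e+01 5.801022e-02 3.809407e-01 5.522289e+01 5.478419e+01
2.305162e+00 4.778061e+01 6.031118e-02 3.680199e-01 4.820894e+01 4.778088e+01
2.408746e+00 4.165868e+01 6.259235e-02 3.553090e-01 4.207658e+01 4.165897e+01
2.516985e+00 3.630905e+01 6.484817e-02 3.428468e-01 3.671675e+01 3.630937e+01
2.630087e+00 3.163592e+01 6.707333e-02 3.306669e-01 3.203366e+01 3.163626e+01
2.748272e+00 2.755513e+01 6.926287e-02 3.187983e-01 2.794319e+01 2.755550e+01
2.871767e+00 2.399283e+01 7.141220e-02 3.072654e-01 2.437151e+01 2.399322e+01
3.000812e+00 2.088419e+01 7.351710e-02 2.960886e-01 2.125380e+01 2.088462e+01
3.135655e+00 1.817239e+01 7.557480e-02 2.852822e-01 1.853324e+01 1.817284e+01
3.276558e+00 1.580774e+01 7.758689e-02 2.748493e-01 1.616017e+01 1.580823e+01
3.423792e+00 1.374664e+01 7.955691e-02 2.647889e-01 1.409098e+01 1.374716e+01
3.577643e+00 1.195083e+01 8.148946e-02 2.550993e-01 1.228742e+01 1.195139e+01
3.738406e+00 1.038676e+01 8.339009e-02 2.457773e-01 1.071593e+01 1.038736e+01
3.906394e+00 9.025030e+00 8.526536e-02 2.368186e-01 9.347113e+00 9.025671e+00
4.081931e+00 7.839863e+00 8.712263e-02 2.282174e-01 8.155203e+00 7.840547e+00
4.265355e+00 6.808672e+00 8.896818e-02 2.199583e-01 7.117598e+00 6.809401e+00
4.457021e+00 5.911666e+00 9.080686e-02 2.120162e-01 6.214489e+00 5.912443e+00
4.657301e+00 5.131568e+00 9.264384e-02 2.043679e-01 5.428580e+00 5.132396e+00
4.866579e+00 4.453301e+00 9.448485e-02 1.969919e-01 4.744778e+00 4.454183e+00
5.085262e+00 3.863715e+00 9.633615e-02 1.898688e-01 4.149920e+00 3.864653e+00
5.313772e+00 3.351353e+00 9.820195e-02 1.829735e-01 3.632528e+00 3.352351e+00
5.552550e+00 2.906230e+00 1.000832e-01 1.762733e-01 3.182587e+00 2.907293e+00
5.802057e+00 2.519638e+00 1.019808e-01 1.697395e-01 2.791359e+00 2.520768e+00
6.062777e+00 2.183979e+00 1.038956e-01 1.633471e-01 2.451221e+00 2.185180e+00
6.335212e+00 1.892626e+00 1.058277e-01 1.570765e-01 2.155530e+00 1.893903e+00
6.619889e+00 1.639791e+00 1.077749e-01 1.509152e-01 1.898481e+00 1.641149e+00
6.917358e+00 1.420438e+00 1.097346e-01 1.448533e-01 1.675026e+00 1.421880e+00
7.228194e+00 1.230179e+00 1.117041e-01 1.388831e-01 1.480766e+00 1.231711e+00
7.552997e+00 1.065195e+00 1.136805e-01 1.329987e-01 1.311875e+00 1.066823e+00
7.892396e+00 9.221634e-01 1.156607e-01 1.271965e-01 1.165021e+00 9.238912e-01
8.247046e+00 7.981871e-01 1.176412e-01 1.214745e-01 1.037303e+00 8.000208e-01
8.617633e+00 6.907523e-01 1.196163e-01 1.158376e-01 9.262062e-01 6.926975e-01
9.004872e+00 5.976714e-01 1.215788e-01 1.102935e-01 8.295437e-01 5.997341e-01
9.409512e+00 5.170425e-01 1.235207e-01 1.048502e-01 7.454134e-01 5.192286e-01
9.832334e+00 4.472130e-01 1.254340e-01 9.951524e-02 6.721623e-01 4.495288e-01
1.027416e+01 3.867493e-01 1.273103e-01 9.429645e-02 6.083560e-01 3.892008e-01
1.073583e+01 3.344051e-01 1.291431e-01 8.920608e-02 5.527543e-01 3.369988e-01
1.121825e+01 2.890991e-01 1.309273e-01 8.425832e-02 5.042847e-01 2.918413e-01
1.172235e+01 2.498927e-01 1.326580e-01 7.946514e-02 4.620158e-01 2.527901e-01
1.224911e+01 2.159715e-01 1.343299e-01 7.483634e-02 4.251377e-01 2.190306e-01
1.279953e+01 1.866284e-01 1.359379e-01 7.037959e-02 3.929459e-01 1.898561e-01
1.337468e+01 1.612504e-01 1.374768e-01 6.610064e-02 3.648278e-01 1.646533e-01
1.397568e+01 1.393054e-01 1.389414e-01 6.200344e-02 3.402502e-01 1.428904e-01
1.460369e+01 1.203322e-01 1.403265e-01 5.809027e-02 3.187489e-01 1.241061e-01
1.525992e+01 1.039310e-01 1.416268e-01 5.436191e-02 2.999197e-01 1.079006e-01
1.594563e+01 8.975490e-02 1.428391e-01 5.081794e-02 2.834119e-01 9.392688e-02
1.666216e+01 7.750344e-02 1.439627e-01 4.745696e-02 2.689231e-01 8.188463e-02
1.741088e+01 6.691636e-02 1.449972e-01 4.427642e-02 2.561900e-01 7.151361e-02
1.819325e+01 5.776848e-02 1.459426e-01 4.127279e-02 2.449838e-01 6.258866e-02
1.901078e+01 4.986498e-02 1.467988e-01 3.844176e-02 2.351056e-01 5.491498e-02
1.986504e+01 4.303732e-02 1.475663e-01 3.577830e-02 2.263819e-01 4.832403e-02
2.075769e+01 3.714031e-02 1.482456e-01 3.327697e-02 2.186629e-01 4.267064e-02
2.169045e+01 3.204755e-02 1.488383e-01 3.093040e-02 2.118163e-01 3.782841e-02
2.266512e+01 2.765014e-02 1.493463e-01 2.873107e-02 2.057275e-01 3.368845e-02
2.368360e+01 2.385382e-02 1.497717e-01 2.667169e-02 2.002972e-01 3.015656e-02
2.474783e+01 2.057699e-02 1.501170e-01 2.474507e-02 1.954390e-01 2.715113e-02
2.585989e+01 1.774903e-02 1.503845e-01 2.294427e-02 1.910778e-01 2.460155e-02
2.702193e+01 1.530880e-02 1.505771e-01 2.126252e-02 1.871484e-01 2.244671e-02
2.823617e+01 1.320343e-02 1.506975e-01 1.969324e-02 1.835941e-01 2.063373e-02
2.950498e+01 1.138719e-02 1.507485e-01 1.823013e-02 1.803658e-01 1.911691e-02
3.083081e+01 9.820172e-03 1.507332e-01 1.686673e-02 1.774201e-01 1.785633e-02
3.221621e+01 8.468334e-03 1.506532e-01 1.559731e-02 1.747188e-01 1.681789e-02
3.366387e+01 7.302210e-03 1.505093e-01 1.441636e-02 1.722279e-01 1.597197e-02
3.517658e+01 6.296213e-03 1.503026e-01 1.331843e-02 1.699173e-01 1.529283e-02
3.675726e+01 5.428311e-03 1.500340e-01 1.229833e-02 1.677606e-01 1.475827e-02
3.840897e+01 4.679523e-03 1.497044e-01 1.135114e-02 1.657351e-01 1.434910e-02
4.013491e+01 4.033518e-03 1.493152e-01 1.047221e-02 1.638209e-01 1.404876e-02
4.193839e+01 3.476507e-03 1.488678e-01 9.657493e-03 1.620018e-01 1.384326e-02
4.382292e+01 2.996257e-03 1.483643e-01 8.902374e-03 1.602629e-01 1.372014e-02
4.579214e+01 2.582444e-03 1.478071e-01 8.202940e-03 1.585925e-01 1.366889e-02
4.784984e+01 2.226063e-03 1.471986e-01 7.555483e-03 1.569802e-01 1.368030e-02
5.000000e+01 1.919277e-03 1.465413e-01 6.956498e-03 1.554171e-01 1.374631e-02
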