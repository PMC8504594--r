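# Photon mass interaction coefficients for Ti (Z=22), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 5.864941e+03 1.181900e-02 3.691529e+00 5.868645e+03 5.864831e+03
1.044936e+00 5.245074e+03 1.251008e-02 3.661351e+00 5.248748e+03 5.244979e+03
1.091891e+00 4.690701e+03 1.323914e-02 3.631129e+00 4.694345e+03 4.690619e+03
1.140955e+00 4.194921e+03 1.400553e-02 3.600582e+00 4.198536e+03 4.194852e+03
1.192225e+00 3.751543e+03 1.480814e-02 3.569435e+00 3.755127e+03 3.751483e+03
1.245798e+00 3.355027e+03 1.564524e-02 3.537427e+00 3.358580e+03 3.354976e+03
1.301779e+00 3.000420e+03 1.651451e-02 3.504306e+00 3.003941e+03 3.000377e+03
1.360275e+00 2.683294e+03 1.741288e-02 3.469831e+00 2.686781e+03 2.683256e+03
1.421400e+00 2.399685e+03 1.833654e-02 3.433773e+00 2.403138e+03 2.399654e+03
1.485272e+00 2.146053e+03 1.928087e-02 3.395919e+00 2.149468e+03 2.146026e+03
1.552014e+00 1.913627e+03 2.024100e-02 3.356089e+00 1.917003e+03 1.913604e+03
1.621754e+00 1.704931e+03 2.121665e-02 3.314323e+00 1.708266e+03 1.704911e+03
1.694629e+00 1.518994e+03 2.221043e-02 3.270763e+00 1.522287e+03 1.518977e+03
1.770778e+00 1.353336e+03 2.322569e-02 3.225545e+00 1.356585e+03 1.353322e+03
1.850349e+00 1.205744e+03 2.426655e-02 3.178807e+00 1.208947e+03 1.205732e+03
1.933496e+00 1.074248e+03 2.533793e-02 3.130686e+00 1.077404e+03 1.074237e+03
2.020379e+00 9.564403e+02 2.644562e-02 3.081318e+00 9.595481e+02 9.564315e+02
2.111166e+00 8.496183e+02 2.759440e-02 3.030781e+00 8.526767e+02 8.496108e+02
2.206033e+00 7.547269e+02 2.878567e-02 2.979032e+00 7.577347e+02 7.547206e+02
2.305162e+00 6.704337e+02 3.002032e-02 2.926026e+00 6.733897e+02 6.704283e+02
2.408746e+00 5.955549e+02 3.129921e-02 2.871731e+00 5.984579e+02 5.955504e+02
2.516985e+00 5.290391e+02 3.262313e-02 2.816124e+00 5.318879e+02 5.290353e+02
2.630087e+00 4.699523e+02 3.399285e-02 2.759196e+00 4.727455e+02 4.699491e+02
2.748272e+00 4.174647e+02 3.540908e-02 2.700946e+00 4.202010e+02 4.174620e+02
2.871767e+00 3.708393e+02 3.687245e-02 2.641386e+00 3.735175e+02 3.708370e+02
3.000812e+00 3.294166e+02 3.838356e-02 2.580540e+00 3.320355e+02 3.294148e+02
3.135655e+00 2.919401e+02 3.994274e-02 2.518451e+00 2.944984e+02 2.919385e+02
3.276558e+00 2.587271e+02 4.154943e-02 2.455219e+00 2.612238e+02 2.587258e+02
3.423792e+00 2.292926e+02 4.320264e-02 2.390957e+00 2.317268e+02 2.292916e+02
3.577643e+00 2.032068e+02 4.490110e-02 2.325782e+00 2.055775e+02 2.032060e+02
3.738406e+00 1.800887e+02 4.664323e-02 2.259815e+00 1.823952e+02 1.800881e+02
3.906394e+00 1.596006e+02 4.842712e-02 2.193181e+00 1.618423e+02 1.596002e+02
4.081931e+00 1.413437e+02 5.025057e-02 2.126007e+00 1.435200e+02 1.413435e+02
4.265355e+00 1.250722e+02 5.211186e-02 2.058447e+00 1.271828e+02 1.250721e+02
4.457021e+00 1.106739e+02 5.400995e-02 1.990677e+00 1.127186e+02 1.106739e+02
4.657301e+00 9.793306e+01 5.594379e-02 1.922870e+00 9.991187e+01 9.793316e+01
4.866579e+00 8.665898e+01 5.791220e-02 1.855191e+00 8.857208e+01 8.665918e+01
4.965400e+00 8.194484e+01 5.882359e-02 1.824324e+00 8.382798e+01 8.194508e+01
4.967400e+00 6.857022e+02 5.884192e-02 1.823707e+00 6.875847e+02 5.620122e+02
5.085262e+00 6.689146e+02 5.991381e-02 1.787800e+00 6.707623e+02 5.510494e+02
5.313772e+00 6.157563e+02 6.194638e-02 1.720905e+00 6.175392e+02 5.119238e+02
5.552550e+00 5.477431e+02 6.400636e-02 1.654773e+00 5.494619e+02 4.593515e+02
5.802057e+00 4.785406e+02 6.608971e-02 1.589643e+00 4.801964e+02 4.046375e+02
6.062777e+00 4.173121e+02 6.819199e-02 1.525731e+00 4.189061e+02 3.556364e+02
6.335212e+00 3.670955e+02 7.030855e-02 1.463219e+00 3.686290e+02 3.151747e+02
6.619889e+00 3.254699e+02 7.243470e-02 1.402259e+00 3.269446e+02 2.814163e+02
6.917358e+00 2.902039e+02 7.456548e-02 1.342979e+00 2.916214e+02 2.526130e+02
7.228194e+00 2.596586e+02 7.669560e-02 1.285486e+00 2.610208e+02 2.274710e+02
7.552997e+00 2.326249e+02 7.881946e-02 1.229862e+00 2.339336e+02 2.050287e+02
7.892396e+00 2.082142e+02 8.093115e-02 1.176175e+00 2.094713e+02 1.845763e+02
8.247046e+00 1.858151e+02 8.302474e-02 1.124465e+00 1.870226e+02 1.656275e+02
8.617633e+00 1.652876e+02 8.509679e-02 1.074718e+00 1.664474e+02 1.481026e+02
9.004872e+00 1.466608e+02 8.714565e-02 1.026890e+00 1.477748e+02 1.320685e+02
9.409512e+00 1.299075e+02 8.916986e-02 9.809340e-01 1.309776e+02 1.175383e+02
9.832334e+00 1.149562e+02 9.116820e-02 9.368015e-01 1.159842e+02 1.044816e+02
1.027416e+01 1.017014e+02 9.313963e-02 8.944393e-01 1.026890e+02 9.283349e+01
1.073583e+01 8.997770e+01 9.508352e-02 8.537302e-01 9.092652e+01 8.246980e+01
1.121825e+01 7.960205e+01 9.699960e-02 8.145240e-01 8.051358e+01 7.324596e+01
1.172235e+01 7.041428e+01 9.888782e-02 7.766891e-01 7.128985e+01 6.503403e+01
1.224911e+01 6.227443e+01 1.007484e-01 7.401117e-01 6.311529e+01 5.772122e+01
1.279953e+01 5.506008e+01 1.025816e-01 7.046943e-01 5.586735e+01 5.120797e+01
1.337468e+01 4.866397e+01 1.043883e-01 6.703540e-01 4.943871e+01 4.540627e+01
1.397568e+01 4.299196e+01 1.061693e-01 6.370218e-01 4.373515e+01 4.023829e+01
1.460369e+01 3.796135e+01 1.079258e-01 6.046412e-01 3.867391e+01 3.563503e+01
1.525992e+01 3.349935e+01 1.096590e-01 5.731676e-01 3.418218e+01 3.153538e+01
1.594563e+01 2.954337e+01 1.113682e-01 5.425974e-01 3.019734e+01 2.788647e+01
1.666216e+01 2.603939e+01 1.130494e-01 5.129691e-01 2.666541e+01 2.464250e+01
1.741088e+01 2.293871e+01 1.146983e-01 4.843163e-01 2.353773e+01 2.176181e+01
1.819325e+01 2.019737e+01 1.163105e-01 4.566659e-01 2.077034e+01 1.920646e+01
1.901078e+01 1.777577e+01 1.178815e-01 4.300378e-01 1.832369e+01 1.694199e+01
1.986504e+01 1.563831e+01 1.194067e-01 4.044460e-01 1.616216e+01 1.493720e+01
2.075769e+01 1.375316e+01 1.208817e-01 3.799043e-01 1.425394e+01 1.316398e+01
2.169045e+01 1.209111e+01 1.223026e-01 3.564358e-01 1.256985e+01 1.159637e+01
2.266512e+01 1.062624e+01 1.236663e-01 3.340622e-01 1.108397e+01 1.021114e+01
2.368360e+01 9.335594e+00 1.249695e-01 3.127938e-01 9.773357e+00 8.987650e+00
2.474783e+01 8.198831e+00 1.262088e-01 2.926307e-01 8.617671e+00 7.907503e+00
2.585989e+01 7.197950e+00 1.273812e-01 2.735636e-01 7.598895e+00 6.954345e+00
2.702193e+01 6.317011e+00 1.284835e-01 2.555758e-01 6.701070e+00 6.113629e+00
2.823617e+01 5.541910e+00 1.295128e-01 2.386437e-01 5.910066e+00 5.372428e+00
2.950498e+01 4.860169e+00 1.304660e-01 2.227383e-01 5.213373e+00 4.719259e+00
3.083081e+01 4.260623e+00 1.313405e-01 2.078220e-01 4.599786e+00 4.143798e+00
3.221621e+01 3.733661e+00 1.321359e-01 1.938490e-01 4.059646e+00 3.637138e+00
3.366387e+01 3.270797e+00 1.328538e-01 1.807669e-01 3.584418e+00 3.191389e+00
3.517658e+01 2.864428e+00 1.334959e-01 1.685236e-01 3.166448e+00 2.799454e+00
3.675726e+01 2.507823e+00 1.340641e-01 1.570696e-01 2.798956e+00 2.455025e+00
3.840897e+01 2.195022e+00 1.345606e-01 1.463580e-01 2.475940e+00 2.152505e+00
4.013491e+01 1.920769e+00 1.349875e-01 1.363445e-01 2.192101e+00 1.886940e+00
4.193839e+01 1.680496e+00 1.353466e-01 1.269901e-01 1.942833e+00 1.654016e+00
4.382292e+01 1.469920e+00 1.356373e-01 1.182457e-01 1.723803e+00 1.449668e+00
4.579214e+01 1.285398e+00 1.358587e-01 1.100704e-01 1.531327e+00 1.270436e+00
4.784984e+01 1.123733e+00 1.360097e-01 1.024263e-01 1.362169e+00 1.113274e+00
5.000000e+01 9.821215e-01 1.360898e-01 9.527821e-02 1.213489e+00 9.755045e-01
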