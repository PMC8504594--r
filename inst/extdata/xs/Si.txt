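# Photon mass interaction coefficients for Si (Z=14), 1-50 keV
# Columns: energy_keV photoelectric_cm2g incoherent_cm2g coherent_cm2g total_cm2g energy_absorption_cm2g
# total = photoelectric + incoherent + coherent; log-log interpolation intended;
# absorption-edge energies appear as paired nodes at edge -/+ 0.001 keV
# energy_absorption = photoelectric*(1 - fluorescence escape) + incoherent*<T>/E
1.000000e+00 1.567441e+03 1.316758e-02 2.528031e+00 1.569983e+03 1.567441e+03
1.044936e+00 1.394540e+03 1.408913e-02 2.504238e+00 1.397058e+03 1.394539e+03
1.091891e+00 1.240707e+03 1.507207e-02 2.480408e+00 1.243203e+03 1.240707e+03
1.140955e+00 1.103844e+03 1.611694e-02 2.456292e+00 1.106317e+03 1.103844e+03
1.192225e+00 9.820786e+02 1.722359e-02 2.431647e+00 9.845275e+02 9.820783e+02
1.245798e+00 8.737450e+02 1.839105e-02 2.406242e+00 8.761696e+02 8.737448e+02
1.301779e+00 7.773617e+02 1.961742e-02 2.379858e+00 7.797612e+02 7.773615e+02
1.360275e+00 6.916105e+02 2.089971e-02 2.352286e+00 6.939837e+02 6.916104e+02
1.421400e+00 6.153186e+02 2.223370e-02 2.323333e+00 6.176641e+02 6.153185e+02
1.485272e+00 5.474424e+02 2.361386e-02 2.292816e+00 5.497589e+02 5.474424e+02
1.552014e+00 4.862253e+02 2.503376e-02 2.260596e+00 4.885109e+02 4.862253e+02
1.621754e+00 4.316409e+02 2.648989e-02 2.226752e+00 4.338942e+02 4.316409e+02
1.694629e+00 3.831843e+02 2.798049e-02 2.191459e+00 3.854037e+02 3.831843e+02
1.770778e+00 3.401675e+02 2.950379e-02 2.154892e+00 3.423519e+02 3.401675e+02
1.837900e+00 3.075533e+02 3.081741e-02 2.123072e+00 3.097072e+02 3.075534e+02
1.839900e+00 3.188138e+03 3.085614e-02 2.122131e+00 3.190291e+03 3.050922e+03
1.850349e+00 3.159772e+03 3.105807e-02 2.117221e+00 3.161920e+03 3.024544e+03
1.933496e+00 2.943515e+03 3.264159e-02 2.078611e+00 2.945626e+03 2.822959e+03
2.020379e+00 2.722519e+03 3.425268e-02 2.039221e+00 2.724592e+03 2.615809e+03
2.111166e+00 2.490495e+03 3.588949e-02 1.999196e+00 2.492530e+03 2.397077e+03
2.206033e+00 2.255551e+03 3.754975e-02 1.958647e+00 2.257547e+03 2.174585e+03
2.305162e+00 2.025705e+03 3.923106e-02 1.917682e+00 2.027662e+03 1.956116e+03
2.408746e+00 1.807009e+03 4.093101e-02 1.876403e+00 1.808926e+03 1.747603e+03
2.516985e+00 1.603648e+03 4.264722e-02 1.834910e+00 1.605525e+03 1.553194e+03
2.630087e+00 1.418164e+03 4.437730e-02 1.793294e+00 1.420002e+03 1.375465e+03
2.748272e+00 1.251748e+03 4.611892e-02 1.751647e+00 1.253545e+03 1.215680e+03
2.871767e+00 1.104547e+03 4.786983e-02 1.710053e+00 1.106304e+03 1.074089e+03
3.000812e+00 9.759607e+02 4.962783e-02 1.668591e+00 9.776789e+02 9.502061e+02
3.135655e+00 8.645573e+02 5.139140e-02 1.627330e+00 8.662360e+02 8.427237e+02
3.276558e+00 7.675897e+02 5.316144e-02 1.586310e+00 7.692292e+02 7.490387e+02
3.423792e+00 6.825482e+02 5.493994e-02 1.545564e+00 6.841487e+02 6.667619e+02
3.577643e+00 6.074370e+02 5.672950e-02 1.505123e+00 6.089989e+02 5.939922e+02
3.738406e+00 5.406645e+02 5.853330e-02 1.465019e+00 5.421880e+02 5.292123e+02
3.906394e+00 4.809590e+02 6.035518e-02 1.425279e+00 4.824446e+02 4.712096e+02
4.081931e+00 4.273104e+02 6.219959e-02 1.385931e+00 4.287585e+02 4.190211e+02
4.265355e+00 3.790782e+02 6.407036e-02 1.346956e+00 3.804892e+02 3.720409e+02
4.457021e+00 3.358709e+02 6.597035e-02 1.308291e+00 3.372452e+02 3.299040e+02
4.657301e+00 2.972990e+02 6.790278e-02 1.269881e+00 2.986368e+02 2.922446e+02
4.866579e+00 2.629730e+02 6.987125e-02 1.231681e+00 2.642745e+02 2.586945e+02
5.085262e+00 2.325109e+02 7.187974e-02 1.193652e+00 2.337764e+02 2.288908e+02
5.313772e+00 2.055174e+02 7.393107e-02 1.155745e+00 2.067470e+02 2.024554e+02
5.552550e+00 1.815956e+02 7.602615e-02 1.117886e+00 1.827896e+02 1.790066e+02
5.802057e+00 1.603935e+02 7.816574e-02 1.080021e+00 1.615517e+02 1.582053e+02
6.062777e+00 1.416009e+02 8.035062e-02 1.042107e+00 1.427234e+02 1.397523e+02
6.335212e+00 1.249472e+02 8.258073e-02 1.004139e+00 1.260339e+02 1.233864e+02
6.619889e+00 1.101970e+02 8.485403e-02 9.661634e-01 1.112480e+02 1.088798e+02
6.917358e+00 9.714037e+01 8.716801e-02 9.282342e-01 9.815577e+01 9.602947e+01
7.228194e+00 8.558973e+01 8.951986e-02 8.904115e-01 8.656966e+01 8.465328e+01
7.552997e+00 7.537719e+01 9.190641e-02 8.527580e-01 7.632186e+01 7.458822e+01
7.892396e+00 6.635280e+01 9.432418e-02 8.153394e-01 6.726246e+01 6.568845e+01
8.247046e+00 5.838257e+01 9.676908e-02 7.782271e-01 5.925757e+01 5.782348e+01
8.617633e+00 5.134744e+01 9.923532e-02 7.415413e-01 5.218822e+01 5.087721e+01
9.004872e+00 4.514128e+01 1.017156e-01 7.054194e-01 4.594841e+01 4.474603e+01
9.409512e+00 3.966940e+01 1.042021e-01 6.699844e-01 4.044359e+01 3.933739e+01
9.832334e+00 3.484749e+01 1.066862e-01 6.353444e-01 3.558952e+01 3.456880e+01
1.027416e+01 3.060057e+01 1.091590e-01 6.015952e-01 3.131132e+01 3.036681e+01
1.073583e+01 2.686162e+01 1.116124e-01 5.688337e-01 2.754206e+01 2.666572e+01
1.121825e+01 2.357106e+01 1.140395e-01 5.371510e-01 2.422225e+01 2.340706e+01
1.172235e+01 2.067618e+01 1.164329e-01 5.066202e-01 2.129923e+01 2.053905e+01
1.224911e+01 1.813033e+01 1.187852e-01 4.772968e-01 1.872641e+01 1.801582e+01
1.279953e+01 1.589225e+01 1.210885e-01 4.492200e-01 1.646256e+01 1.579680e+01
1.337468e+01 1.392545e+01 1.233348e-01 4.224148e-01 1.447120e+01 1.384605e+01
1.397568e+01 1.219768e+01 1.255159e-01 3.968931e-01 1.272009e+01 1.213181e+01
1.460369e+01 1.068045e+01 1.276233e-01 3.726550e-01 1.118073e+01 1.062597e+01
1.525992e+01 9.348585e+00 1.296486e-01 3.496906e-01 9.827925e+00 9.303706e+00
1.594563e+01 8.179907e+00 1.315865e-01 3.279729e-01 8.639466e+00 8.143127e+00
1.666216e+01 7.154899e+00 1.334365e-01 3.074599e-01 7.595795e+00 7.124955e+00
1.741088e+01 6.256298e+00 1.351985e-01 2.881071e-01 6.679604e+00 6.232129e+00
1.819325e+01 5.468853e+00 1.368732e-01 2.698686e-01 5.875595e+00 5.449570e+00
1.901078e+01 4.779100e+00 1.384613e-01 2.526982e-01 5.170259e+00 4.763956e+00
1.986504e+01 4.175159e+00 1.399640e-01 2.365491e-01 4.551673e+00 4.163530e+00
2.075769e+01 3.646600e+00 1.413831e-01 2.213750e-01 4.009358e+00 3.637963e+00
2.169045e+01 3.184110e+00 1.427193e-01 2.071194e-01 3.533949e+00 3.178028e+00
2.266512e+01 2.779531e+00 1.439734e-01 1.937266e-01 3.117231e+00 2.775641e+00
2.368360e+01 2.425706e+00 1.451466e-01 1.811451e-01 2.751998e+00 2.423704e+00
2.474783e+01 2.116351e+00 1.462403e-01 1.693267e-01 2.431918e+00 2.115984e+00
2.585989e+01 1.845950e+00 1.472560e-01 1.582260e-01 2.151432e+00 1.847007e+00
2.702193e+01 1.609660e+00 1.481957e-01 1.478007e-01 1.905656e+00 1.611968e+00
2.823617e+01 1.403235e+00 1.490612e-01 1.380110e-01 1.690307e+00 1.406649e+00
2.950498e+01 1.222948e+00 1.498550e-01 1.288196e-01 1.501623e+00 1.227350e+00
3.083081e+01 1.065498e+00 1.505795e-01 1.201891e-01 1.336267e+00 1.070790e+00
3.221621e+01 9.280565e-01 1.512348e-01 1.120861e-01 1.191377e+00 9.341571e-01
3.366387e+01 8.081456e-01 1.518200e-01 1.044786e-01 1.064444e+00 8.149898e-01
3.517658e+01 7.035678e-01 1.523339e-01 9.733564e-02 9.532374e-01 7.111022e-01
3.675726e+01 6.123944e-01 1.527757e-01 9.062879e-02 8.557989e-01 6.205755e-01
3.840897e+01 5.329335e-01 1.531445e-01 8.433164e-02 7.704096e-01 5.417265e-01
4.013491e+01 4.637048e-01 1.534396e-01 7.841998e-02 6.955643e-01 4.730817e-01
4.193839e+01 4.034314e-01 1.536600e-01 7.287469e-02 6.299660e-01 4.133701e-01
4.382292e+01 3.509334e-01 1.538052e-01 6.767552e-02 5.724142e-01 3.614164e-01
4.579214e+01 3.052127e-01 1.538747e-01 6.280626e-02 5.218936e-01 3.162265e-01
4.784984e+01 2.653991e-01 1.538676e-01 5.825085e-02 4.775175e-01 2.769331e-01
5.000000e+01 2.307338e-01 1.537835e-01 5.399346e-02 4.385107e-01 2.427799e-01
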