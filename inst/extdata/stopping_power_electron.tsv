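# Electron collision (electronic) stopping power, soft tissue / liquid water surrogate
# Source: Berger-Seltzer collision stopping-power formula (ESTAR-compatible),
#   mean excitation energy I = 75 eV, Z/A = 0.555; density effect neglected (< 2.5 MeV).
# Radiative (bremsstrahlung) losses excluded: photons are not transported.
# reference_density_g_cm3: 1.000
# particle: electron
# columns: energy_MeV stopping_power_MeV_cm2_g
# version: 1
1.00000e-03 1.19757e+02
1.06796e-03 1.14844e+02
1.14053e-03 1.10073e+02
1.21804e-03 1.05447e+02
1.30082e-03 1.00966e+02
1.38922e-03 9.66311e+01
1.48363e-03 9.24412e+01
1.58445e-03 8.83957e+01
1.69213e-03 8.44931e+01
1.80712e-03 8.07317e+01
1.92993e-03 7.71094e+01
2.06108e-03 7.36238e+01
2.20115e-03 7.02721e+01
2.35073e-03 6.70515e+01
2.51049e-03 6.39589e+01
2.68109e-03 6.09910e+01
2.86329e-03 5.81446e+01
3.05788e-03 5.54162e+01
3.26568e-03 5.28024e+01
3.48761e-03 5.02997e+01
3.72462e-03 4.79045e+01
3.97774e-03 4.56134e+01
4.24806e-03 4.34229e+01
4.53675e-03 4.13294e+01
4.84506e-03 3.93295e+01
5.17432e-03 3.74198e+01
5.52595e-03 3.55970e+01
5.90148e-03 3.38577e+01
6.30254e-03 3.21988e+01
6.73084e-03 3.06171e+01
7.18826e-03 2.91096e+01
7.67675e-03 2.76732e+01
8.19845e-03 2.63050e+01
8.75560e-03 2.50023e+01
9.35061e-03 2.37622e+01
9.98606e-03 2.25820e+01
1.06647e-02 2.14593e+01
1.13894e-02 2.03916e+01
1.21634e-02 1.93763e+01
1.29900e-02 1.84113e+01
1.38728e-02 1.74942e+01
1.48156e-02 1.66229e+01
1.58224e-02 1.57954e+01
1.68977e-02 1.50096e+01
1.80460e-02 1.42636e+01
1.92724e-02 1.35555e+01
2.05821e-02 1.28837e+01
2.19808e-02 1.22464e+01
2.34746e-02 1.16419e+01
2.50699e-02 1.10688e+01
2.67735e-02 1.05255e+01
2.85930e-02 1.00106e+01
3.05361e-02 9.52268e+00
3.26113e-02 9.06051e+00
3.48275e-02 8.62281e+00
3.71943e-02 8.20839e+00
3.97220e-02 7.81610e+00
4.24214e-02 7.44486e+00
4.53042e-02 7.09363e+00
4.83830e-02 6.76142e+00
5.16710e-02 6.44729e+00
5.51825e-02 6.15032e+00
5.89326e-02 5.86968e+00
6.29375e-02 5.60454e+00
6.72146e-02 5.35413e+00
7.17823e-02 5.11770e+00
7.66605e-02 4.89455e+00
8.18702e-02 4.68402e+00
8.74339e-02 4.48546e+00
9.33758e-02 4.29828e+00
9.97214e-02 4.12190e+00
1.06498e-01 3.95578e+00
1.13736e-01 3.79939e+00
1.21465e-01 3.65225e+00
1.29719e-01 3.51388e+00
1.38535e-01 3.38386e+00
1.47949e-01 3.26175e+00
1.58004e-01 3.14716e+00
1.68741e-01 3.03971e+00
1.80209e-01 2.93905e+00
1.92455e-01 2.84483e+00
2.05534e-01 2.75674e+00
2.19502e-01 2.67446e+00
2.34418e-01 2.59771e+00
2.50349e-01 2.52621e+00
2.67362e-01 2.45971e+00
2.85532e-01 2.39795e+00
3.04936e-01 2.34071e+00
3.25658e-01 2.28776e+00
3.47790e-01 2.23888e+00
3.71425e-01 2.19389e+00
3.96666e-01 2.15257e+00
4.23622e-01 2.11477e+00
4.52411e-01 2.08029e+00
4.83156e-01 2.04897e+00
5.15990e-01 2.02066e+00
5.51055e-01 1.99520e+00
5.88504e-01 1.97246e+00
6.28497e-01 1.95228e+00
6.71209e-01 1.93454e+00
7.16823e-01 1.91911e+00
7.65536e-01 1.90587e+00
8.17561e-01 1.89469e+00
8.73120e-01 1.88548e+00
9.32456e-01 1.87811e+00
9.95823e-01 1.87248e+00
1.06350e+00 1.86850e+00
1.13577e+00 1.86606e+00
1.21296e+00 1.86508e+00
1.29538e+00 1.86546e+00
1.38342e+00 1.86712e+00
1.47743e+00 1.86997e+00
1.57783e+00 1.87395e+00
1.68506e+00 1.87896e+00
1.79957e+00 1.88496e+00
1.92187e+00 1.89185e+00
2.05247e+00 1.89959e+00
2.19196e+00 1.90811e+00
2.34092e+00 1.91734e+00
2.50000e+00 1.92725e+00
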