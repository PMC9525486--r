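# Alpha-particle electronic stopping power, soft tissue / liquid water surrogate
# Source: anchor reconstruction of standard range-energy tabulations (ASTAR-class)
#   for liquid water; velocity-proportional extrapolation below the ~0.8 MeV peak.
# reference_density_g_cm3: 1.000
# particle: alpha
# columns: energy_MeV stopping_power_MeV_cm2_g
# version: 1
1.00000e-03 7.99031e+01
1.25345e-03 8.94575e+01
1.57114e-03 1.00154e+02
1.96934e-03 1.12130e+02
2.46847e-03 1.25539e+02
3.09410e-03 1.40550e+02
3.87830e-03 1.57356e+02
4.86125e-03 1.76172e+02
6.09333e-03 1.97238e+02
7.63768e-03 2.20823e+02
9.57345e-03 2.47228e+02
1.19998e-02 2.76790e+02
1.50412e-02 3.09888e+02
1.88534e-02 3.46943e+02
2.36317e-02 3.88429e+02
2.96212e-02 4.34875e+02
3.71287e-02 4.86876e+02
4.65389e-02 5.45094e+02
5.83342e-02 6.10274e+02
7.31189e-02 6.83248e+02
9.16509e-02 7.64948e+02
1.14880e-01 8.56417e+02
1.43996e-01 9.58823e+02
1.80492e-01 1.07348e+03
2.26237e-01 1.20184e+03
2.83577e-01 1.34555e+03
3.55449e-01 1.50644e+03
4.45538e-01 1.68657e+03
5.58459e-01 1.88825e+03
7.00000e-01 2.11404e+03
8.00000e-01 2.26000e+03
1.00000e+00 2.19000e+03
1.50000e+00 1.95000e+03
2.00000e+00 1.70000e+03
2.50000e+00 1.45000e+03
3.00000e+00 1.27000e+03
3.50000e+00 1.13000e+03
4.00000e+00 1.02000e+03
4.50000e+00 9.30000e+02
5.00000e+00 8.55000e+02
5.50000e+00 7.90000e+02
6.00000e+00 7.35000e+02
6.50000e+00 6.90000e+02
7.00000e+00 6.50000e+02
7.50000e+00 6.15000e+02
8.00000e+00 5.83000e+02
8.50000e+00 5.55000e+02
9.00000e+00 5.30000e+02
9.50000e+00 5.07000e+02
1.00000e+01 4.87000e+02
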