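# Fe (Z=26) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.702158e+02
10.348734 1.553610e+02
10.709630 1.417654e+02
11.083111 1.293257e+02
11.469617 1.179469e+02
11.869602 1.075415e+02
12.283536 9.802904e+01
12.711904 8.933526e+01
13.155212 8.139201e+01
13.613979 7.413567e+01
14.088745 6.750887e+01
14.580068 6.143617e+01
15.088525 5.589109e+01
15.614713 5.083762e+01
16.159251 4.623237e+01
16.722780 4.203664e+01
17.305960 3.821556e+01
17.909478 3.473636e+01
18.534043 3.156911e+01
19.180388 2.868641e+01
19.849274 2.606321e+01
20.541486 2.367664e+01
21.257838 2.150578e+01
21.999171 1.953154e+01
22.766357 1.773646e+01
23.560298 1.610461e+01
24.381926 1.462145e+01
25.232207 1.327351e+01
26.112140 1.204788e+01
27.022760 1.093274e+01
27.965136 9.918310e+00
28.940376 8.998091e+00
29.949625 8.163575e+00
30.994071 7.405935e+00
32.074940 6.714821e+00
33.193503 6.089323e+00
34.351074 5.523248e+00
35.549013 5.010973e+00
36.788729 4.547398e+00
38.071678 4.127903e+00
39.399367 3.748300e+00
40.773358 3.404799e+00
42.195264 3.093967e+00
43.666757 2.812698e+00
45.189566 2.558178e+00
46.765480 2.327864e+00
48.396353 2.119451e+00
50.084099 1.930853e+00
51.830702 1.760185e+00
53.638216 1.605737e+00
55.508764 1.465964e+00
57.444544 1.339466e+00
59.447832 1.224977e+00
61.520981 1.121352e+00
63.666427 1.027551e+00
65.886693 9.426374e-01
68.184387 8.657603e-01
70.562210 7.961511e-01
73.022955 7.331140e-01
75.569515 6.760193e-01
78.204882 6.242975e-01
80.932154 5.774331e-01
83.754535 5.349599e-01
86.675341 4.964560e-01
89.698007 4.615399e-01
92.826083 4.298669e-01
96.063245 4.011242e-01
99.413299 3.750299e-01
102.880180 3.513292e-01
106.467964 3.297906e-01
110.180865 3.102063e-01
114.023249 2.923872e-01
117.999629 2.761629e-01
122.114679 2.613796e-01
126.373235 2.478980e-01
130.780302 2.355926e-01
135.341058 2.243491e-01
140.060863 2.140660e-01
144.945263 2.046493e-01
150.000000 1.960164e-01
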