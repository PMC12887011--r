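# Ar (Z=18) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 6.249764e+01
10.348734 5.670511e+01
10.709630 5.144183e+01
11.083111 4.666033e+01
11.469617 4.231730e+01
11.869602 3.837318e+01
12.283536 3.479206e+01
12.711904 3.154113e+01
13.155212 2.859049e+01
13.613979 2.591287e+01
14.088745 2.347809e+01
14.580068 2.126453e+01
15.088525 1.925899e+01
15.614713 1.744216e+01
16.159251 1.579649e+01
16.722780 1.430604e+01
17.305960 1.295634e+01
17.909478 1.173426e+01
18.534043 1.062787e+01
19.180388 9.626355e+00
19.849274 8.719887e+00
20.541486 7.899551e+00
21.257838 7.157256e+00
21.999171 6.485661e+00
22.766357 5.878108e+00
23.560298 5.328553e+00
24.381926 4.831518e+00
25.232207 4.381944e+00
26.112140 3.974937e+00
27.022760 3.606569e+00
27.965136 3.273303e+00
28.940376 2.971916e+00
29.949625 2.699426e+00
30.994071 2.453110e+00
32.074940 2.230481e+00
33.193503 2.029282e+00
34.351074 1.847460e+00
35.549013 1.683154e+00
36.788729 1.534678e+00
38.071678 1.400507e+00
39.399367 1.279259e+00
40.773358 1.169686e+00
42.195264 1.070659e+00
43.666757 9.811569e-01
45.189566 9.002578e-01
46.765480 8.271280e-01
48.396353 7.610145e-01
50.084099 7.012366e-01
51.830702 6.471792e-01
53.638216 5.982868e-01
55.508764 5.540571e-01
57.444544 5.140367e-01
59.447832 4.778156e-01
61.520981 4.450236e-01
63.666427 4.153263e-01
65.886693 3.884215e-01
68.184387 3.640365e-01
70.562210 3.419247e-01
73.022955 3.218637e-01
75.569515 3.036524e-01
78.204882 2.871095e-01
80.932154 2.720712e-01
83.754535 2.583897e-01
86.675341 2.459315e-01
89.698007 2.345762e-01
92.826083 2.242154e-01
96.063245 2.147507e-01
99.413299 2.060939e-01
102.880180 1.981654e-01
106.467964 1.908930e-01
110.180865 1.842123e-01
114.023249 1.780644e-01
117.999629 1.723969e-01
122.114679 1.671623e-01
126.373235 1.623177e-01
130.780302 1.578248e-01
135.341058 1.536486e-01
140.060863 1.497583e-01
144.945263 1.461252e-01
150.000000 1.427244e-01
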