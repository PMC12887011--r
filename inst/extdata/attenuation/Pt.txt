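# Pt (Z=78) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.104439e+02
10.348734 1.012438e+02
10.709630 9.281491e+01
11.083111 8.509211e+01
11.469617 7.801550e+01
11.563700 7.643079e+01
11.563700 1.943982e+02
11.863700 1.815934e+02
11.869602 1.813522e+02
12.283536 1.654665e+02
12.563700 1.557663e+02
12.711904 1.509443e+02
13.155212 1.376701e+02
13.272600 1.344451e+02
13.272600 1.863409e+02
13.572600 1.755231e+02
13.613979 1.740947e+02
13.879900 1.653184e+02
13.879900 1.906356e+02
14.088745 1.836534e+02
14.179900 1.807065e+02
14.272600 1.777748e+02
14.563700 1.689761e+02
14.580068 1.684954e+02
14.879900 1.600125e+02
15.088525 1.544534e+02
15.614713 1.415649e+02
16.159251 1.297300e+02
16.272600 1.274383e+02
16.722780 1.188647e+02
16.879900 1.160586e+02
17.305960 1.088909e+02
17.909478 9.973092e+01
18.534043 9.132885e+01
19.180388 8.362309e+01
19.849274 7.655711e+01
20.541486 7.007898e+01
21.257838 6.414086e+01
21.999171 5.869869e+01
22.766357 5.371194e+01
23.560298 4.914257e+01
24.381926 4.495709e+01
25.232207 4.112298e+01
26.112140 3.760429e+01
27.022760 3.437188e+01
27.965136 3.140250e+01
28.940376 2.868472e+01
29.949625 2.620103e+01
30.994071 2.393196e+01
32.074940 2.185940e+01
33.193503 1.996658e+01
34.351074 1.823808e+01
35.549013 1.665970e+01
36.788729 1.521843e+01
38.071678 1.390238e+01
39.399367 1.270066e+01
40.773358 1.160335e+01
42.195264 1.060135e+01
43.666757 9.686403e+00
45.189566 8.850934e+00
46.765480 8.088048e+00
48.396353 7.391447e+00
50.084099 6.755382e+00
51.830702 6.173901e+00
53.638216 5.643152e+00
55.508764 5.158719e+00
57.444544 4.716557e+00
59.447832 4.312619e+00
61.520981 3.943465e+00
63.666427 3.606566e+00
65.886693 3.299384e+00
68.184387 3.019282e+00
70.562210 2.763860e+00
73.022955 2.530928e+00
75.569515 2.318492e+00
78.204882 2.124738e+00
78.394798 2.111761e+00
78.394798 9.116135e+00
78.694798 9.024353e+00
79.394798 8.819183e+00
80.932154 8.421577e+00
81.394798 8.309671e+00
83.754535 7.741440e+00
86.675341 7.093907e+00
89.698007 6.500189e+00
92.826083 5.955898e+00
96.063245 5.456993e+00
99.413299 4.999761e+00
102.880180 4.579959e+00
106.467964 4.193704e+00
110.180865 3.840499e+00
114.023249 3.517525e+00
117.999629 3.222205e+00
122.114679 2.952181e+00
126.373235 2.705293e+00
130.780302 2.479567e+00
135.341058 2.273189e+00
140.060863 2.084513e+00
144.945263 1.912013e+00
150.000000 1.754313e+00
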