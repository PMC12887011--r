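# Yb (Z=70) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.939222e+02
10.348734 2.663343e+02
10.486400 2.566559e+02
10.486400 2.960239e+02
10.709630 2.808736e+02
10.786400 2.758826e+02
11.083111 2.576316e+02
11.469617 2.360998e+02
11.486400 2.352215e+02
11.869602 2.163109e+02
12.283536 1.981355e+02
12.711904 1.814536e+02
13.155212 1.661355e+02
13.486400 1.558143e+02
13.613979 1.520723e+02
14.088745 1.391749e+02
14.580068 1.273529e+02
15.088525 1.165189e+02
15.614713 1.065921e+02
16.159251 9.749820e+01
16.722780 8.916880e+01
17.305960 8.154096e+01
17.909478 7.455653e+01
18.534043 6.815646e+01
19.180388 6.230018e+01
19.849274 5.694220e+01
20.541486 5.203693e+01
21.257838 4.754985e+01
21.999171 4.344643e+01
22.766357 3.969583e+01
23.560298 3.626797e+01
24.381926 3.313533e+01
25.232207 3.027136e+01
26.112140 2.764724e+01
27.022760 2.524147e+01
27.965136 2.303666e+01
28.940376 2.102323e+01
29.949625 1.918547e+01
30.994071 1.750862e+01
32.074940 1.597892e+01
33.193503 1.458367e+01
34.351074 1.331113e+01
35.549013 1.215055e+01
36.788729 1.109208e+01
38.071678 1.012670e+01
39.399367 9.245454e+00
40.773358 8.441133e+00
42.195264 7.707759e+00
43.666757 7.038685e+00
45.189566 6.427899e+00
46.765480 5.869323e+00
48.396353 5.360122e+00
50.084099 4.896222e+00
51.830702 4.473559e+00
53.638216 4.088437e+00
55.508764 3.737495e+00
57.444544 3.417677e+00
59.447832 3.126201e+00
61.332298 2.883474e+00
61.332298 1.350663e+01
61.520981 1.340455e+01
61.632298 1.334448e+01
62.332298 1.297463e+01
63.666427 1.230583e+01
64.332298 1.198876e+01
65.886693 1.127369e+01
68.184387 1.032035e+01
70.562210 9.447362e+00
73.022955 8.648040e+00
75.569515 7.916239e+00
78.204882 7.246326e+00
80.932154 6.631107e+00
83.754535 6.064590e+00
86.675341 5.546622e+00
89.698007 5.073089e+00
92.826083 4.640225e+00
96.063245 4.244572e+00
99.413299 3.882966e+00
102.880180 3.552511e+00
106.467964 3.250547e+00
110.180865 2.974646e+00
114.023249 2.722577e+00
117.999629 2.492301e+00
122.114679 2.281952e+00
126.373235 2.085853e+00
130.780302 1.906933e+00
135.341058 1.744226e+00
140.060863 1.596248e+00
144.945263 1.461634e+00
150.000000 1.339165e+00
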