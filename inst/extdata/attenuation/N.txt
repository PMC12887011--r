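# N (Z=7) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 3.750429e+00
10.348734 3.392571e+00
10.709630 3.071050e+00
11.083111 2.782160e+00
11.469617 2.522574e+00
11.869602 2.289302e+00
12.283536 2.079653e+00
12.711904 1.891218e+00
13.155212 1.721833e+00
13.613979 1.569549e+00
14.088745 1.432620e+00
14.580068 1.309475e+00
15.088525 1.198707e+00
15.614713 1.099049e+00
16.159251 1.009367e+00
16.722780 9.286416e-01
17.305960 8.559582e-01
17.909478 7.904961e-01
18.534043 7.315190e-01
19.180388 6.783660e-01
19.849274 6.304441e-01
20.541486 5.872214e-01
21.257838 5.482203e-01
21.999171 5.130125e-01
22.766357 4.812133e-01
23.560298 4.524776e-01
24.381926 4.264955e-01
25.232207 4.029723e-01
26.112140 3.815921e-01
27.022760 3.621196e-01
27.965136 3.443729e-01
28.940376 3.282991e-01
29.949625 3.137386e-01
30.994071 3.005426e-01
32.074940 2.885740e-01
33.193503 2.777073e-01
34.351074 2.678287e-01
35.549013 2.588354e-01
36.788729 2.506349e-01
38.071678 2.431443e-01
39.399367 2.362894e-01
40.773358 2.300036e-01
42.195264 2.242277e-01
43.666757 2.189086e-01
45.189566 2.139988e-01
46.765480 2.094561e-01
48.396353 2.052424e-01
50.084099 2.013238e-01
51.830702 1.976698e-01
53.638216 1.942533e-01
55.508764 1.910497e-01
57.444544 1.880370e-01
59.447832 1.851957e-01
61.520981 1.825078e-01
63.666427 1.799576e-01
65.886693 1.775306e-01
68.184387 1.752139e-01
70.562210 1.729961e-01
73.022955 1.708666e-01
75.569515 1.688161e-01
78.204882 1.668361e-01
80.932154 1.649191e-01
83.754535 1.630582e-01
86.675341 1.612473e-01
89.698007 1.594809e-01
92.826083 1.577542e-01
96.063245 1.560626e-01
99.413299 1.544022e-01
102.880180 1.527696e-01
106.467964 1.511615e-01
110.180865 1.495752e-01
114.023249 1.480082e-01
117.999629 1.464582e-01
122.114679 1.449234e-01
126.373235 1.434021e-01
130.780302 1.418927e-01
135.341058 1.403938e-01
140.060863 1.389045e-01
144.945263 1.374236e-01
150.000000 1.359504e-01
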