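# C (Z=6) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.293278e+00
10.348734 2.081958e+00
10.709630 1.892243e+00
11.083111 1.721900e+00
11.469617 1.568926e+00
11.869602 1.431526e+00
12.283536 1.308088e+00
12.711904 1.197168e+00
13.155212 1.097472e+00
13.613979 1.007840e+00
14.088745 9.272314e-01
14.580068 8.547153e-01
15.088525 7.894566e-01
15.614713 7.307074e-01
16.159251 6.777980e-01
16.722780 6.301283e-01
17.305960 5.871611e-01
17.909478 5.484152e-01
18.534043 5.134594e-01
19.180388 4.819079e-01
19.849274 4.534145e-01
20.541486 4.276694e-01
21.257838 4.043947e-01
21.999171 3.833410e-01
22.766357 3.642848e-01
23.560298 3.470252e-01
24.381926 3.313818e-01
25.232207 3.171823e-01
26.112140 3.042376e-01
27.022760 2.924038e-01
27.965136 2.815726e-01
28.940376 2.717212e-01
29.949625 2.627552e-01
30.994071 2.545870e-01
32.074940 2.471357e-01
33.193503 2.403276e-01
34.351074 2.340960e-01
35.549013 2.283804e-01
36.788729 2.231268e-01
38.071678 2.182865e-01
39.399367 2.138162e-01
40.773358 2.096770e-01
42.195264 2.058340e-01
43.666757 2.022564e-01
45.189566 1.989164e-01
46.765480 1.957890e-01
48.396353 1.928522e-01
50.084099 1.900861e-01
51.830702 1.874726e-01
53.638216 1.849960e-01
55.508764 1.826417e-01
57.444544 1.803969e-01
59.447832 1.782499e-01
61.520981 1.761902e-01
63.666427 1.742086e-01
65.886693 1.722964e-01
68.184387 1.704461e-01
70.562210 1.686509e-01
73.022955 1.669045e-01
75.569515 1.652015e-01
78.204882 1.635367e-01
80.932154 1.619058e-01
83.754535 1.603047e-01
86.675341 1.587298e-01
89.698007 1.571779e-01
92.826083 1.556461e-01
96.063245 1.541317e-01
99.413299 1.526326e-01
102.880180 1.511467e-01
106.467964 1.496721e-01
110.180865 1.482074e-01
114.023249 1.467511e-01
117.999629 1.453020e-01
122.114679 1.438590e-01
126.373235 1.424213e-01
130.780302 1.409880e-01
135.341058 1.395586e-01
140.060863 1.381324e-01
144.945263 1.367091e-01
150.000000 1.352883e-01
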