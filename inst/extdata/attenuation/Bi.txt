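# Bi (Z=83) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.327927e+02
10.348734 1.217823e+02
10.709630 1.116882e+02
11.083111 1.024340e+02
11.469617 9.394642e+01
11.869602 8.616076e+01
12.283536 7.902149e+01
12.711904 7.247791e+01
13.155212 6.647921e+01
13.418600 6.325298e+01
13.418600 1.557256e+02
13.613979 1.498898e+02
13.718600 1.468704e+02
14.088745 1.368161e+02
14.418600 1.286099e+02
14.580068 1.248351e+02
15.088525 1.138849e+02
15.614713 1.038778e+02
15.711100 1.021926e+02
15.711100 1.421140e+02
16.011100 1.352115e+02
16.159251 1.319567e+02
16.387501 1.271668e+02
16.387501 1.465206e+02
16.418600 1.458514e+02
16.687501 1.400537e+02
16.711100 1.395600e+02
16.722780 1.393165e+02
17.305960 1.278374e+02
17.387501 1.263254e+02
17.909478 1.172120e+02
18.534043 1.074557e+02
18.711100 1.048937e+02
19.180388 9.849687e+01
19.387501 9.584378e+01
19.849274 9.027200e+01
20.541486 8.272208e+01
21.257838 7.579238e+01
21.999171 6.943550e+01
22.766357 6.360374e+01
23.560298 5.825462e+01
24.381926 5.334913e+01
25.232207 4.884967e+01
26.112140 4.471598e+01
27.022760 4.091463e+01
27.965136 3.741825e+01
28.940376 3.421704e+01
29.949625 3.128731e+01
30.994071 2.860683e+01
32.074940 2.615101e+01
33.193503 2.390162e+01
34.351074 2.184316e+01
35.549013 1.996234e+01
36.788729 1.824389e+01
38.071678 1.667381e+01
39.399367 1.523928e+01
40.773358 1.392862e+01
42.195264 1.273113e+01
43.666757 1.163704e+01
45.189566 1.063743e+01
46.765480 9.724147e+00
48.396353 8.889756e+00
50.084099 8.127454e+00
51.830702 7.431029e+00
53.638216 6.794804e+00
55.508764 6.213593e+00
57.444544 5.682655e+00
59.447832 5.197329e+00
61.520981 4.753976e+00
63.666427 4.349152e+00
65.886693 3.979506e+00
68.184387 3.641973e+00
70.562210 3.333694e+00
73.022955 3.052078e+00
75.569515 2.795073e+00
78.204882 2.560564e+00
80.932154 2.346568e+00
83.754535 2.151280e+00
86.675341 1.973051e+00
89.698007 1.810378e+00
90.526001 1.769288e+00
90.526001 7.233156e+00
90.826001 7.174167e+00
91.526001 7.038627e+00
92.826083 6.796075e+00
93.526001 6.670230e+00
96.063245 6.239970e+00
99.413299 5.728252e+00
102.880180 5.257524e+00
106.467964 4.822750e+00
110.180865 4.423703e+00
114.023249 4.057707e+00
117.999629 3.722071e+00
122.114679 3.414319e+00
126.373235 3.132170e+00
130.780302 2.872149e+00
135.341058 2.633480e+00
140.060863 2.415258e+00
144.945263 2.215715e+00
150.000000 2.033254e+00
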