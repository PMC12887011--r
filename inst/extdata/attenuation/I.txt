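# I (Z=53) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.606968e+02
10.348734 1.466800e+02
10.709630 1.338582e+02
11.083111 1.221475e+02
11.469617 1.114542e+02
11.869602 1.016905e+02
12.283536 9.277633e+01
12.711904 8.463956e+01
13.155212 7.721312e+01
13.613979 7.043557e+01
14.088745 6.425073e+01
14.580068 5.860719e+01
15.088525 5.345792e+01
15.614713 4.875993e+01
16.159251 4.447392e+01
16.722780 4.056336e+01
17.305960 3.699579e+01
17.909478 3.374122e+01
18.534043 3.077276e+01
19.180388 2.806558e+01
19.849274 2.559648e+01
20.541486 2.334372e+01
21.257838 2.128951e+01
21.999171 1.941623e+01
22.766357 1.770849e+01
23.560298 1.615171e+01
24.381926 1.473318e+01
25.232207 1.344002e+01
26.112140 1.225854e+01
27.022760 1.117607e+01
27.965136 1.018313e+01
28.940376 9.279646e+00
29.949625 8.457867e+00
30.994071 7.710574e+00
32.074940 7.031080e+00
33.169399 6.426249e+00
33.169399 3.592078e+01
33.469399 3.509164e+01
34.169399 3.325065e+01
34.351074 3.279460e+01
35.549013 2.999942e+01
36.169399 2.868057e+01
36.788729 2.744126e+01
38.071678 2.509589e+01
39.399367 2.294612e+01
40.773358 2.097612e+01
42.195264 1.917130e+01
43.666757 1.751722e+01
45.189566 1.600141e+01
46.765480 1.461427e+01
48.396353 1.334518e+01
50.084099 1.218436e+01
51.830702 1.112281e+01
53.638216 1.015227e+01
55.508764 9.265155e+00
57.444544 8.454474e+00
59.447832 7.713822e+00
61.520981 7.037309e+00
63.666427 6.419527e+00
65.886693 5.855511e+00
68.184387 5.339861e+00
70.562210 4.869568e+00
73.022955 4.440934e+00
75.569515 4.050326e+00
78.204882 3.694418e+00
80.932154 3.368620e+00
83.754535 3.069566e+00
86.675341 2.798004e+00
89.698007 2.551395e+00
92.826083 2.327433e+00
96.063245 2.124024e+00
99.413299 1.939272e+00
102.880180 1.771454e+00
106.467964 1.619003e+00
110.180865 1.480504e+00
114.023249 1.354667e+00
117.999629 1.240322e+00
122.114679 1.136410e+00
126.373235 1.041967e+00
130.780302 9.561201e-01
135.341058 8.780745e-01
140.060863 8.071137e-01
144.945263 7.425800e-01
150.000000 6.838840e-01
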