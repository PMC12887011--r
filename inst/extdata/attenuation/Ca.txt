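# Ca (Z=20) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 9.256957e+01
10.348734 8.410119e+01
10.709630 7.639464e+01
11.083111 6.938278e+01
11.469617 6.300425e+01
11.869602 5.720292e+01
12.283536 5.192764e+01
12.711904 4.713166e+01
13.155212 4.277228e+01
13.613979 3.881051e+01
14.088745 3.521078e+01
14.580068 3.194064e+01
15.088525 2.897046e+01
15.614713 2.627327e+01
16.159251 2.382443e+01
16.722780 2.160152e+01
17.305960 1.958407e+01
17.909478 1.774926e+01
18.534043 1.608412e+01
19.180388 1.457511e+01
19.849274 1.320778e+01
20.541486 1.196901e+01
21.257838 1.084684e+01
21.999171 9.830438e+00
22.766357 8.909957e+00
23.560298 8.076457e+00
24.381926 7.321818e+00
25.232207 6.638565e+00
26.112140 6.019571e+00
27.022760 5.456603e+00
27.965136 4.943490e+00
28.940376 4.480050e+00
29.949625 4.061538e+00
30.994071 3.683637e+00
32.074940 3.342426e+00
33.193503 3.034349e+00
34.351074 2.756188e+00
35.549013 2.505031e+00
36.788729 2.278246e+00
38.071678 2.073457e+00
39.399367 1.888519e+00
40.773358 1.721493e+00
42.195264 1.570633e+00
43.666757 1.434360e+00
45.189566 1.311252e+00
46.765480 1.200023e+00
48.396353 1.099515e+00
50.084099 1.008682e+00
51.830702 9.265803e-01
53.638216 8.523581e-01
55.508764 7.852468e-01
57.444544 7.245526e-01
59.447832 6.696492e-01
61.520981 6.199716e-01
63.666427 5.750096e-01
65.886693 5.343028e-01
68.184387 4.974357e-01
70.562210 4.640330e-01
73.022955 4.337563e-01
75.569515 4.062999e-01
78.204882 3.813882e-01
80.932154 3.587722e-01
83.754535 3.382272e-01
86.675341 3.195507e-01
89.698007 3.025596e-01
92.826083 2.870890e-01
96.063245 2.729899e-01
99.413299 2.601279e-01
102.880180 2.483820e-01
106.467964 2.376426e-01
110.180865 2.278114e-01
114.023249 2.187992e-01
117.999629 2.105258e-01
122.114679 2.029191e-01
126.373235 1.959137e-01
130.780302 1.894511e-01
135.341058 1.834779e-01
140.060863 1.779470e-01
144.945263 1.728146e-01
150.000000 1.680426e-01
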