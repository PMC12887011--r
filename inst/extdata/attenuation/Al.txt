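# Al (Z=13) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.564446e+01
10.348734 2.318248e+01
10.709630 2.095671e+01
11.083111 1.894472e+01
11.469617 1.712618e+01
11.869602 1.548268e+01
12.283536 1.399753e+01
12.711904 1.265562e+01
13.155212 1.144327e+01
13.613979 1.034807e+01
14.088745 9.358818e+00
14.580068 8.465339e+00
15.088525 7.658438e+00
15.614713 6.929789e+00
16.159251 6.271860e+00
16.722780 5.677832e+00
17.305960 5.141539e+00
17.909478 4.657403e+00
18.534043 4.220380e+00
19.180388 3.825908e+00
19.849274 3.469865e+00
20.541486 3.148525e+00
21.257838 2.858517e+00
21.999171 2.596800e+00
22.766357 2.360624e+00
23.560298 2.147503e+00
24.381926 1.955193e+00
25.232207 1.781590e+00
26.112140 1.624524e+00
27.022760 1.482447e+00
27.965136 1.354010e+00
28.940376 1.238038e+00
29.949625 1.133356e+00
30.994071 1.038885e+00
32.074940 9.536354e-01
33.193503 8.767078e-01
34.351074 8.072839e-01
35.549013 7.446225e-01
36.788729 6.880537e-01
38.071678 6.369727e-01
39.399367 5.908340e-01
40.773358 5.491459e-01
42.195264 5.114658e-01
43.666757 4.773948e-01
45.189566 4.465741e-01
46.765480 4.186805e-01
48.396353 3.934231e-01
50.084099 3.705399e-01
51.830702 3.497951e-01
53.638216 3.309763e-01
55.508764 3.138923e-01
57.444544 2.983707e-01
59.447832 2.842563e-01
61.520981 2.714094e-01
63.666427 2.597041e-01
65.886693 2.490268e-01
68.184387 2.392753e-01
70.562210 2.303576e-01
73.022955 2.221906e-01
75.569515 2.146995e-01
78.204882 2.078170e-01
80.932154 2.014824e-01
83.754535 1.956410e-01
86.675341 1.902436e-01
89.698007 1.852458e-01
92.826083 1.806078e-01
96.063245 1.762933e-01
99.413299 1.722701e-01
102.880180 1.685090e-01
106.467964 1.649837e-01
110.180865 1.616708e-01
114.023249 1.585488e-01
117.999629 1.555986e-01
122.114679 1.528032e-01
126.373235 1.501470e-01
130.780302 1.476164e-01
135.341058 1.451986e-01
140.060863 1.428829e-01
144.945263 1.406587e-01
150.000000 1.385176e-01
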