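# Gd (Z=64) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.660556e+02
10.348734 2.435460e+02
10.709630 2.228768e+02
11.083111 2.039280e+02
11.469617 1.865603e+02
11.869602 1.706464e+02
12.283536 1.560676e+02
12.711904 1.427142e+02
13.155212 1.304856e+02
13.613979 1.192889e+02
14.088745 1.090391e+02
14.580068 9.965471e+01
15.088525 9.105657e+01
15.614713 8.319256e+01
16.159251 7.599495e+01
16.722780 6.941082e+01
17.305960 6.338753e+01
17.909478 5.788413e+01
18.534043 5.285648e+01
19.180388 4.826385e+01
19.849274 4.406891e+01
20.541486 4.023750e+01
21.257838 3.673833e+01
21.999171 3.354277e+01
22.766357 3.062463e+01
23.560298 2.795994e+01
24.381926 2.552681e+01
25.232207 2.330411e+01
26.112140 2.126901e+01
27.022760 1.940574e+01
27.965136 1.770122e+01
28.940376 1.614590e+01
29.949625 1.472746e+01
30.994071 1.343432e+01
32.074940 1.225436e+01
33.193503 1.117861e+01
34.351074 1.019862e+01
35.549013 9.304097e+00
36.788729 8.488142e+00
38.071678 7.743408e+00
39.399367 7.065504e+00
40.773358 6.448359e+00
42.195264 5.886457e+00
43.666757 5.374792e+00
45.189566 4.908817e+00
46.765480 4.484407e+00
48.396353 4.097812e+00
50.084099 3.745630e+00
50.239101 3.715659e+00
50.239101 1.847553e+01
50.539101 1.820232e+01
51.239101 1.758311e+01
51.830702 1.708114e+01
53.239101 1.595282e+01
53.638216 1.564826e+01
55.508764 1.432185e+01
57.444544 1.310575e+01
59.447832 1.199103e+01
61.520981 1.096947e+01
63.666427 1.003348e+01
65.886693 9.176172e+00
68.184387 8.391177e+00
70.562210 7.672315e+00
73.022955 7.014171e+00
75.569515 6.411760e+00
78.204882 5.860493e+00
80.932154 5.355520e+00
83.754535 4.892931e+00
86.675341 4.470527e+00
89.698007 4.084860e+00
92.826083 3.732777e+00
96.063245 3.411387e+00
99.413299 3.118047e+00
102.880180 2.846253e+00
106.467964 2.597353e+00
110.180865 2.371162e+00
114.023249 2.165582e+00
117.999629 1.978713e+00
122.114679 1.808834e+00
126.373235 1.654379e+00
130.780302 1.513931e+00
135.341058 1.386200e+00
140.060863 1.270022e+00
144.945263 1.164330e+00
150.000000 1.068169e+00
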