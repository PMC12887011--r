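# O (Z=8) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 5.771220e+00
10.348734 5.212237e+00
10.709630 4.709519e+00
11.083111 4.257353e+00
11.469617 3.850706e+00
11.869602 3.485003e+00
12.283536 3.156115e+00
12.711904 2.860328e+00
13.155212 2.594300e+00
13.613979 2.355022e+00
14.088745 2.139791e+00
14.580068 1.946174e+00
15.088525 1.771981e+00
15.614713 1.615247e+00
16.159251 1.474203e+00
16.722780 1.347257e+00
17.305960 1.232983e+00
17.909478 1.130094e+00
18.534043 1.037438e+00
19.180388 9.539765e-01
19.849274 8.787791e-01
20.541486 8.110089e-01
21.257838 7.499144e-01
21.999171 6.948206e-01
22.766357 6.451215e-01
23.560298 6.002727e-01
24.381926 5.597856e-01
25.232207 5.231931e-01
26.112140 4.899840e-01
27.022760 4.597800e-01
27.965136 4.322935e-01
28.940376 4.074546e-01
29.949625 3.850124e-01
30.994071 3.647328e-01
32.074940 3.463994e-01
33.193503 3.298146e-01
34.351074 3.147986e-01
35.549013 3.011892e-01
36.788729 2.888400e-01
38.071678 2.776199e-01
39.399367 2.674113e-01
40.773358 2.581088e-01
42.195264 2.496184e-01
43.666757 2.418559e-01
45.189566 2.347459e-01
46.765480 2.282213e-01
48.396353 2.222218e-01
50.084099 2.166936e-01
51.830702 2.115882e-01
53.638216 2.068625e-01
55.508764 2.024776e-01
57.444544 1.983988e-01
59.447832 1.945947e-01
61.520981 1.910374e-01
63.666427 1.877016e-01
65.886693 1.845646e-01
68.184387 1.816060e-01
70.562210 1.788076e-01
73.022955 1.761529e-01
75.569515 1.736270e-01
78.204882 1.712166e-01
80.932154 1.689097e-01
83.754535 1.666956e-01
86.675341 1.645646e-01
89.698007 1.625080e-01
92.826083 1.605179e-01
96.063245 1.585874e-01
99.413299 1.567101e-01
102.880180 1.548805e-01
106.467964 1.530935e-01
110.180865 1.513446e-01
114.023249 1.496297e-01
117.999629 1.479453e-01
122.114679 1.462882e-01
126.373235 1.446555e-01
130.780302 1.430448e-01
135.341058 1.414537e-01
140.060863 1.398805e-01
144.945263 1.383231e-01
150.000000 1.367803e-01
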