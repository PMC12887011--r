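# Au (Z=79) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.152363e+02
10.348734 1.056406e+02
10.709630 9.684745e+01
11.083111 8.879102e+01
11.469617 8.140919e+01
11.918700 7.388428e+01
11.918700 1.869989e+02
12.218700 1.748322e+02
12.283536 1.723401e+02
12.711904 1.571447e+02
12.918700 1.505039e+02
13.155212 1.433653e+02
13.613979 1.307700e+02
13.733600 1.277557e+02
13.733600 1.772297e+02
14.033600 1.673087e+02
14.088745 1.655626e+02
14.352800 1.575680e+02
14.352800 1.816725e+02
14.580068 1.746855e+02
14.652800 1.725208e+02
14.733600 1.701584e+02
14.918700 1.649088e+02
15.088525 1.602766e+02
15.352800 1.533700e+02
15.614713 1.469232e+02
16.159251 1.346642e+02
16.722780 1.234082e+02
16.733600 1.232049e+02
17.305960 1.130749e+02
17.352800 1.122971e+02
17.909478 1.035901e+02
18.534043 9.488149e+01
19.180388 8.689394e+01
19.849274 7.956820e+01
20.541486 7.285043e+01
21.257838 6.669128e+01
21.999171 6.104531e+01
22.766357 5.587066e+01
23.560298 5.112884e+01
24.381926 4.678379e+01
25.232207 4.280230e+01
26.112140 3.914780e+01
27.022760 3.579199e+01
27.965136 3.270911e+01
28.940376 2.988557e+01
29.949625 2.730143e+01
30.994071 2.494019e+01
32.074940 2.278308e+01
33.193503 2.081273e+01
34.351074 1.901313e+01
35.549013 1.736956e+01
36.788729 1.586854e+01
38.071678 1.449772e+01
39.399367 1.324580e+01
40.773358 1.210248e+01
42.195264 1.105833e+01
43.666757 1.010476e+01
45.189566 9.233910e+00
46.765480 8.438613e+00
48.396353 7.712325e+00
50.084099 7.049072e+00
51.830702 6.443315e+00
53.638216 5.889596e+00
55.508764 5.384154e+00
57.444544 4.922779e+00
59.447832 4.501628e+00
61.520981 4.116883e+00
63.666427 3.765335e+00
65.886693 3.444522e+00
68.184387 3.151960e+00
70.562210 2.885145e+00
73.022955 2.641799e+00
75.569515 2.419842e+00
78.204882 2.217384e+00
80.724899 2.045998e+00
80.724899 8.730057e+00
80.932154 8.674637e+00
81.024899 8.649873e+00
81.724899 8.466044e+00
83.724899 7.969336e+00
83.754535 7.962279e+00
86.675341 7.306596e+00
89.698007 6.703283e+00
92.826083 6.147574e+00
96.063245 5.635104e+00
99.413299 5.165121e+00
102.880180 4.734177e+00
106.467964 4.339090e+00
110.180865 3.976943e+00
114.023249 3.645039e+00
117.999629 3.338484e+00
122.114679 3.058193e+00
126.373235 2.802005e+00
130.780302 2.567850e+00
135.341058 2.353830e+00
140.060863 2.158220e+00
144.945263 1.979426e+00
150.000000 1.816009e+00
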