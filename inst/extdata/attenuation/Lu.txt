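# Lu (Z=71) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.206340e+02
10.348600 2.013266e+02
10.348600 2.803128e+02
10.648600 2.581163e+02
10.709630 2.539183e+02
10.870400 2.434603e+02
10.870400 2.808671e+02
11.083111 2.676161e+02
11.170400 2.623980e+02
11.348600 2.521630e+02
11.469617 2.454907e+02
11.869602 2.250080e+02
11.870400 2.249695e+02
12.283536 2.061777e+02
12.711904 1.888798e+02
13.155212 1.730004e+02
13.348600 1.666425e+02
13.613979 1.584171e+02
13.870400 1.509826e+02
14.088745 1.450234e+02
14.580068 1.327377e+02
15.088525 1.214750e+02
15.614713 1.111524e+02
16.159251 1.016932e+02
16.722780 9.302667e+01
17.305960 8.508791e+01
17.909478 7.781705e+01
18.534043 7.115855e+01
19.180388 6.505734e+01
19.849274 5.947387e+01
20.541486 5.436486e+01
21.257838 4.968765e+01
21.999171 4.540869e+01
22.766357 4.149520e+01
23.560298 3.791776e+01
24.381926 3.464778e+01
25.232207 3.165769e+01
26.112140 2.891760e+01
27.022760 2.640490e+01
27.965136 2.410132e+01
28.940376 2.199733e+01
29.949625 2.007656e+01
30.994071 1.832366e+01
32.074940 1.672431e+01
33.193503 1.526528e+01
34.351074 1.393436e+01
35.549013 1.272033e+01
36.788729 1.161294e+01
38.071678 1.060281e+01
39.399367 9.681370e+00
40.773358 8.840045e+00
42.195264 8.072100e+00
43.666757 7.371789e+00
45.189566 6.732872e+00
46.765480 6.149488e+00
48.396353 5.616047e+00
50.084099 5.129615e+00
51.830702 4.686421e+00
53.638216 4.282590e+00
55.508764 3.914599e+00
57.444544 3.579243e+00
59.447832 3.273607e+00
61.520981 2.995037e+00
63.313801 2.780795e+00
63.313801 1.289355e+01
63.613801 1.274488e+01
63.666427 1.271893e+01
64.313801 1.240522e+01
65.886693 1.168287e+01
66.313801 1.149597e+01
68.184387 1.070148e+01
70.562210 9.796089e+00
73.022955 8.967608e+00
75.569515 8.209532e+00
78.204882 7.515909e+00
80.932154 6.881403e+00
83.754535 6.297303e+00
86.675341 5.760133e+00
89.698007 5.268994e+00
92.826083 4.819985e+00
96.063245 4.409525e+00
99.413299 4.034341e+00
102.880180 3.691432e+00
106.467964 3.378045e+00
110.180865 3.091665e+00
114.023249 2.829984e+00
117.999629 2.590889e+00
122.114679 2.372449e+00
126.373235 2.172893e+00
130.780302 1.986558e+00
135.341058 1.816845e+00
140.060863 1.662495e+00
144.945263 1.522085e+00
150.000000 1.394340e+00
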