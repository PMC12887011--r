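# Ta (Z=73) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.423031e+02
10.348734 2.174145e+02
10.709630 1.982242e+02
11.083111 1.808085e+02
11.136100 1.785497e+02
11.136100 2.464233e+02
11.436100 2.296109e+02
11.469617 2.278243e+02
11.681500 2.170045e+02
11.681500 2.502344e+02
11.869602 2.405028e+02
11.981500 2.349245e+02
12.136100 2.274995e+02
12.283536 2.206950e+02
12.681500 2.035123e+02
12.711904 2.022758e+02
13.155212 1.853508e+02
13.613979 1.698081e+02
14.088745 1.555410e+02
14.136100 1.542090e+02
14.580068 1.424435e+02
14.681500 1.399260e+02
15.088525 1.304143e+02
15.614713 1.193816e+02
16.159251 1.092663e+02
16.722780 9.999443e+01
17.305960 9.149711e+01
17.909478 8.371103e+01
18.534043 7.657792e+01
19.180388 7.004414e+01
19.849274 6.405974e+01
20.541486 5.857681e+01
21.257838 5.355840e+01
21.999171 4.896576e+01
22.766357 4.476171e+01
23.560298 4.091518e+01
24.381926 3.739691e+01
25.232207 3.417878e+01
26.112140 3.122900e+01
27.022760 2.852264e+01
27.965136 2.603970e+01
28.940376 2.377127e+01
29.949625 2.169980e+01
30.994071 1.980881e+01
32.074940 1.808298e+01
33.193503 1.650809e+01
34.351074 1.507108e+01
35.549013 1.375992e+01
36.788729 1.256360e+01
38.071678 1.147206e+01
39.399367 1.047611e+01
40.773358 9.567352e+00
42.195264 8.738141e+00
43.666757 7.980756e+00
45.189566 7.289340e+00
46.765480 6.658665e+00
48.396353 6.083292e+00
50.084099 5.557721e+00
51.830702 5.077437e+00
53.638216 4.639277e+00
55.508764 4.239969e+00
57.444544 3.876043e+00
59.447832 3.544342e+00
61.520981 3.241993e+00
63.666427 2.966380e+00
65.886693 2.715123e+00
67.416397 2.559518e+00
67.416397 1.162968e+01
67.716397 1.150455e+01
68.184387 1.131197e+01
68.416397 1.121795e+01
70.416397 1.044560e+01
70.562210 1.039186e+01
73.022955 9.518322e+00
75.569515 8.716255e+00
78.204882 7.981390e+00
80.932154 7.308349e+00
83.754535 6.691887e+00
86.675341 6.126941e+00
89.698007 5.606852e+00
92.826083 5.130022e+00
96.063245 4.694049e+00
99.413299 4.295463e+00
102.880180 3.931089e+00
106.467964 3.598009e+00
110.180865 3.293563e+00
114.023249 3.015304e+00
117.999629 2.760998e+00
122.114679 2.528599e+00
126.373235 2.316230e+00
130.780302 2.122180e+00
135.341058 1.944402e+00
140.060863 1.778740e+00
144.945263 1.628041e+00
150.000000 1.490936e+00
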