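# Sm (Z=62) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.476386e+02
10.348734 2.265459e+02
10.709630 2.072150e+02
11.083111 1.895057e+02
11.469617 1.732850e+02
11.869602 1.584306e+02
12.283536 1.448298e+02
12.711904 1.323791e+02
13.155212 1.209834e+02
13.613979 1.105474e+02
14.088745 1.009905e+02
14.580068 9.225134e+01
15.088525 8.424874e+01
15.614713 7.693205e+01
16.159251 7.024113e+01
16.722780 6.412934e+01
17.305960 5.854710e+01
17.909478 5.344895e+01
18.534043 4.879325e+01
19.180388 4.454191e+01
19.849274 4.066005e+01
20.541486 3.711576e+01
21.257838 3.387987e+01
21.999171 3.092567e+01
22.766357 2.822876e+01
23.560298 2.576679e+01
24.381926 2.351941e+01
25.232207 2.146700e+01
26.112140 1.958839e+01
27.022760 1.786946e+01
27.965136 1.629829e+01
28.940376 1.486497e+01
29.949625 1.355569e+01
30.994071 1.236235e+01
32.074940 1.127453e+01
33.193503 1.028259e+01
34.351074 9.376925e+00
35.549013 8.551755e+00
36.788729 7.800851e+00
38.071678 7.117449e+00
39.399367 6.495402e+00
40.773358 5.929125e+00
42.195264 5.413550e+00
43.666757 4.944075e+00
45.189566 4.516525e+00
46.765480 4.127110e+00
46.834202 4.111458e+00
46.834202 2.084526e+01
47.134202 2.051740e+01
47.834202 1.977534e+01
48.396353 1.920420e+01
49.834202 1.782224e+01
50.084099 1.759303e+01
51.830702 1.609804e+01
53.638216 1.472762e+01
55.508764 1.347167e+01
57.444544 1.232089e+01
59.447832 1.126669e+01
61.520981 1.030129e+01
63.666427 9.417440e+00
65.886693 8.608243e+00
68.184387 7.867565e+00
70.562210 7.189762e+00
73.022955 6.569643e+00
75.569515 6.002429e+00
78.204882 5.483730e+00
80.932154 5.009148e+00
83.754535 4.575054e+00
86.675341 4.178837e+00
89.698007 3.817235e+00
92.826083 3.487265e+00
96.063245 3.181431e+00
99.413299 2.901779e+00
102.880180 2.647673e+00
106.467964 2.416756e+00
110.180865 2.206892e+00
114.023249 2.016142e+00
117.999629 1.842745e+00
122.114679 1.685107e+00
126.373235 1.541777e+00
130.780302 1.411442e+00
135.341058 1.292905e+00
140.060863 1.185089e+00
144.945263 1.087003e+00
150.000000 9.977608e-01
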