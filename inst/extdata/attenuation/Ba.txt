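# Ba (Z=56) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 1.845652e+02
10.348734 1.686185e+02
10.709630 1.540121e+02
11.083111 1.406448e+02
11.469617 1.284123e+02
11.869602 1.172256e+02
12.283536 1.069949e+02
12.711904 9.764743e+01
13.155212 8.911165e+01
13.613979 8.131790e+01
14.088745 7.420239e+01
14.580068 6.770672e+01
15.088525 6.177712e+01
15.614713 5.636489e+01
16.159251 5.142548e+01
16.722780 4.691789e+01
17.305960 4.280460e+01
17.909478 3.905135e+01
18.534043 3.562679e+01
19.180388 3.250223e+01
19.849274 2.965149e+01
20.541486 2.705068e+01
21.257838 2.467795e+01
21.999171 2.251337e+01
22.766357 2.053869e+01
23.560298 1.873683e+01
24.381926 1.709353e+01
25.232207 1.559395e+01
26.112140 1.422308e+01
27.022760 1.296678e+01
27.965136 1.181445e+01
28.940376 1.076556e+01
29.949625 9.811227e+00
30.994071 8.943142e+00
32.074940 8.153603e+00
33.193503 7.435519e+00
34.351074 6.782391e+00
35.549013 6.188284e+00
36.788729 5.647793e+00
37.440601 5.390396e+00
37.440601 2.909417e+01
37.740601 2.850882e+01
38.071678 2.787889e+01
38.440601 2.719867e+01
39.399367 2.553009e+01
40.440601 2.386029e+01
40.773358 2.335803e+01
42.195264 2.136643e+01
43.666757 1.954072e+01
45.189566 1.786748e+01
46.765480 1.633434e+01
48.396353 1.492991e+01
50.084099 1.364270e+01
51.830702 1.246420e+01
53.638216 1.138568e+01
55.508764 1.039891e+01
57.444544 9.496281e+00
59.447832 8.670818e+00
61.520981 7.916102e+00
63.666427 7.226235e+00
65.886693 6.595795e+00
68.184387 6.019798e+00
70.562210 5.493669e+00
73.022955 5.013203e+00
75.569515 4.574449e+00
78.204882 4.173981e+00
80.932154 3.806661e+00
83.754535 3.468486e+00
86.675341 3.161305e+00
89.698007 2.882261e+00
92.826083 2.628763e+00
96.063245 2.398456e+00
99.413299 2.189204e+00
102.880180 1.999071e+00
106.467964 1.826294e+00
110.180865 1.669277e+00
114.023249 1.526570e+00
117.999629 1.396855e+00
122.114679 1.278939e+00
126.373235 1.171736e+00
130.780302 1.074262e+00
135.341058 9.856201e-01
140.060863 9.050035e-01
144.945263 8.316699e-01
150.000000 7.649541e-01
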