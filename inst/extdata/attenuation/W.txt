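# W (Z=74) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 9.448286e+01
10.206800 8.969812e+01
10.206800 2.397337e+02
10.348734 2.293470e+02
10.506800 2.185713e+02
10.709630 2.059567e+02
11.083111 1.878965e+02
11.206800 1.823852e+02
11.469617 1.713715e+02
11.544000 1.684570e+02
11.544000 2.327419e+02
11.844000 2.172880e+02
11.869602 2.160310e+02
12.099800 2.052107e+02
12.099800 2.366678e+02
12.283536 2.279483e+02
12.399800 2.226280e+02
12.544000 2.162594e+02
12.711904 2.091434e+02
13.099800 1.937676e+02
13.155212 1.916986e+02
13.206800 1.897995e+02
13.613979 1.756747e+02
14.088745 1.609602e+02
14.544000 1.483891e+02
14.580068 1.474514e+02
15.088525 1.350489e+02
15.099800 1.347899e+02
15.614713 1.236539e+02
16.159251 1.132010e+02
16.722780 1.036166e+02
17.305960 9.483080e+01
17.909478 8.677843e+01
18.534043 7.939962e+01
19.180388 7.263922e+01
19.849274 6.644646e+01
20.541486 6.077390e+01
21.257838 5.557704e+01
21.999171 5.082010e+01
22.766357 4.646644e+01
23.560298 4.248130e+01
24.381926 3.883493e+01
25.232207 3.549819e+01
26.112140 3.243930e+01
27.022760 2.963201e+01
27.965136 2.705542e+01
28.940376 2.470117e+01
29.949625 2.255105e+01
30.994071 2.058800e+01
32.074940 1.879615e+01
33.193503 1.716079e+01
34.351074 1.566838e+01
35.549013 1.430649e+01
36.788729 1.306370e+01
38.071678 1.192960e+01
39.399367 1.089468e+01
40.773358 9.950231e+00
42.195264 9.088337e+00
43.666757 8.301769e+00
45.189566 7.583172e+00
46.765480 6.927156e+00
48.396353 6.328698e+00
50.084099 5.782703e+00
51.830702 5.284005e+00
53.638216 4.828275e+00
55.508764 4.412433e+00
57.444544 4.033410e+00
59.447832 3.687927e+00
61.520981 3.372996e+00
63.666427 3.085898e+00
65.886693 2.824158e+00
68.184387 2.585520e+00
69.525002 2.459560e+00
69.525002 1.106331e+01
69.825002 1.094794e+01
70.525002 1.068334e+01
70.562210 1.066949e+01
72.525002 9.967774e+00
73.022955 9.797795e+00
75.569515 8.970582e+00
78.204882 8.213952e+00
80.932154 7.522769e+00
83.754535 6.891071e+00
86.675341 6.311772e+00
89.698007 5.780635e+00
92.826083 5.290525e+00
96.063245 4.841368e+00
99.413299 4.430690e+00
102.880180 4.055223e+00
106.467964 3.711967e+00
110.180865 3.398185e+00
114.023249 3.111359e+00
117.999629 2.849192e+00
122.114679 2.609578e+00
126.373235 2.390588e+00
130.780302 2.190460e+00
135.341058 2.007572e+00
140.060863 1.839614e+00
144.945263 1.683550e+00
150.000000 1.541563e+00
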