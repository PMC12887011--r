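# Eu (Z=63) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.599737e+02
10.348734 2.379036e+02
10.709630 2.176592e+02
11.083111 1.991015e+02
11.469617 1.820992e+02
11.869602 1.665249e+02
12.283536 1.522614e+02
12.711904 1.392006e+02
13.155212 1.272434e+02
13.613979 1.162986e+02
14.088745 1.062770e+02
14.580068 9.709724e+01
15.088525 8.870228e+01
15.614713 8.101713e+01
16.159251 7.398907e+01
16.722780 6.756050e+01
17.305960 6.168785e+01
17.909478 5.632352e+01
18.534043 5.142394e+01
19.180388 4.694917e+01
19.849274 4.286266e+01
20.541486 3.913097e+01
21.257838 3.572348e+01
21.999171 3.261219e+01
22.766357 2.977147e+01
23.560298 2.717791e+01
24.381926 2.481009e+01
25.232207 2.264740e+01
26.112140 2.066757e+01
27.022760 1.885553e+01
27.965136 1.719866e+01
28.940376 1.568696e+01
29.949625 1.430844e+01
30.994071 1.305024e+01
32.074940 1.190331e+01
33.193503 1.085814e+01
34.351074 9.904532e+00
35.549013 9.034261e+00
36.788729 8.240586e+00
38.071678 7.518206e+00
39.399367 6.860636e+00
40.773358 6.261987e+00
42.195264 5.716911e+00
43.666757 5.220553e+00
45.189566 4.768505e+00
46.765480 4.356767e+00
48.396353 3.981703e+00
48.519001 3.955585e+00
48.519001 1.985616e+01
48.819001 1.955343e+01
49.519001 1.886775e+01
50.084099 1.833681e+01
51.519001 1.706280e+01
51.830702 1.679885e+01
53.638216 1.537300e+01
55.508764 1.406584e+01
57.444544 1.286776e+01
59.447832 1.176989e+01
61.520981 1.076409e+01
63.666427 9.842889e+00
65.886693 8.999421e+00
68.184387 8.227136e+00
70.562210 7.520192e+00
73.022955 6.873211e+00
75.569515 6.281246e+00
78.204882 5.739745e+00
80.932154 5.244045e+00
83.754535 4.790330e+00
86.675341 4.376112e+00
89.698007 3.997996e+00
92.826083 3.652878e+00
96.063245 3.337912e+00
99.413299 3.046061e+00
102.880180 2.778946e+00
106.467964 2.536217e+00
110.180865 2.315628e+00
114.023249 2.115135e+00
117.999629 1.932889e+00
122.114679 1.767210e+00
126.373235 1.616572e+00
130.780302 1.479596e+00
135.341058 1.355021e+00
140.060863 1.241715e+00
144.945263 1.138637e+00
150.000000 1.044853e+00
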