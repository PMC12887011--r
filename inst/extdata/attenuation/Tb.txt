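# Tb (Z=65) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 2.790433e+02
10.348734 2.554774e+02
10.709630 2.338614e+02
11.083111 2.140282e+02
11.469617 1.958423e+02
11.869602 1.791695e+02
12.283536 1.638920e+02
12.711904 1.498958e+02
13.155212 1.370758e+02
13.613979 1.253353e+02
14.088745 1.145854e+02
14.580068 1.047442e+02
15.088525 9.573494e+01
15.614713 8.747979e+01
16.159251 7.992917e+01
16.722780 7.301998e+01
17.305960 6.669782e+01
17.909478 6.091506e+01
18.534043 5.563040e+01
19.180388 5.080232e+01
19.849274 4.639170e+01
20.541486 4.236277e+01
21.257838 3.868273e+01
21.999171 3.532157e+01
22.766357 3.225185e+01
23.560298 2.944843e+01
24.381926 2.688834e+01
25.232207 2.454944e+01
26.112140 2.240773e+01
27.022760 2.044640e+01
27.965136 1.865162e+01
28.940376 1.701377e+01
29.949625 1.551990e+01
30.994071 1.415783e+01
32.074940 1.291621e+01
33.193503 1.178342e+01
34.351074 1.075046e+01
35.549013 9.809368e+00
36.788729 8.950525e+00
38.071678 8.167151e+00
39.399367 7.451596e+00
40.773358 6.800167e+00
42.195264 6.207046e+00
43.666757 5.666950e+00
45.189566 5.175082e+00
46.765480 4.727087e+00
48.396353 4.319011e+00
50.084099 3.947259e+00
51.830702 3.608568e+00
51.995701 3.578912e+00
51.995701 1.761097e+01
52.295701 1.736121e+01
52.995701 1.679413e+01
53.638216 1.629452e+01
54.995701 1.529352e+01
55.508764 1.493125e+01
57.444544 1.366538e+01
59.447832 1.250501e+01
61.520981 1.144157e+01
63.666427 1.046717e+01
65.886693 9.574535e+00
68.184387 8.757101e+00
70.562210 8.008775e+00
73.022955 7.323475e+00
75.569515 6.696039e+00
78.204882 6.121716e+00
80.932154 5.595372e+00
83.754535 5.112893e+00
86.675341 4.672229e+00
89.698007 4.269802e+00
92.826083 3.902336e+00
96.063245 3.566828e+00
99.413299 3.260533e+00
102.880180 2.980937e+00
106.467964 2.721791e+00
110.180865 2.484415e+00
114.023249 2.268678e+00
117.999629 2.072584e+00
122.114679 1.894323e+00
126.373235 1.732253e+00
130.780302 1.584884e+00
135.341058 1.450861e+00
140.060863 1.328964e+00
144.945263 1.218071e+00
150.000000 1.117179e+00
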