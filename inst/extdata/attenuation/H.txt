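# H (Z=1) total mass attenuation coefficient
# Computed from Cromer-Liberman photoabsorption (f'') with
# Klein-Nishina incoherent and IT92 form-factor coherent scattering.
# Duplicated energies mark absorption edges (below, then above).
# energy_keV mu_over_rho_cm2_per_g
10.000000 3.828383e-01
10.348734 3.823334e-01
10.709630 3.818142e-01
11.083111 3.812803e-01
11.469617 3.807312e-01
11.869602 3.801663e-01
12.283536 3.795851e-01
12.711904 3.789872e-01
13.155212 3.783720e-01
13.613979 3.777390e-01
14.088745 3.770877e-01
14.580068 3.764175e-01
15.088525 3.757280e-01
15.614713 3.750186e-01
16.159251 3.742888e-01
16.722780 3.735380e-01
17.305960 3.727657e-01
17.909478 3.719714e-01
18.534043 3.711545e-01
19.180388 3.703145e-01
19.849274 3.694509e-01
20.541486 3.685631e-01
21.257838 3.676506e-01
21.999171 3.667129e-01
22.766357 3.657494e-01
23.560298 3.647597e-01
24.381926 3.637431e-01
25.232207 3.626993e-01
26.112140 3.616276e-01
27.022760 3.605276e-01
27.965136 3.593988e-01
28.940376 3.582407e-01
29.949625 3.570530e-01
30.994071 3.558350e-01
32.074940 3.545864e-01
33.193503 3.533067e-01
34.351074 3.519956e-01
35.549013 3.506526e-01
36.788729 3.492775e-01
38.071678 3.478698e-01
39.399367 3.464292e-01
40.773358 3.449554e-01
42.195264 3.434482e-01
43.666757 3.419073e-01
45.189566 3.403324e-01
46.765480 3.387235e-01
48.396353 3.370803e-01
50.084099 3.354027e-01
51.830702 3.336907e-01
53.638216 3.319442e-01
55.508764 3.301631e-01
57.444544 3.283476e-01
59.447832 3.264977e-01
61.520981 3.246134e-01
63.666427 3.226951e-01
65.886693 3.207428e-01
68.184387 3.187568e-01
70.562210 3.167374e-01
73.022955 3.146849e-01
75.569515 3.125998e-01
78.204882 3.104825e-01
80.932154 3.083334e-01
83.754535 3.061531e-01
86.675341 3.039421e-01
89.698007 3.017011e-01
92.826083 2.994308e-01
96.063245 2.971318e-01
99.413299 2.948050e-01
102.880180 2.924511e-01
106.467964 2.900710e-01
110.180865 2.876656e-01
114.023249 2.852358e-01
117.999629 2.827825e-01
122.114679 2.803068e-01
126.373235 2.778097e-01
130.780302 2.752922e-01
135.341058 2.727555e-01
140.060863 2.702007e-01
144.945263 2.676289e-01
150.000000 2.650412e-01
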