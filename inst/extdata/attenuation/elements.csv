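symbol,Z,atomic_weight,kedge_keV
H,1,1.0079,
C,6,12.0107,
N,7,14.0067,
O,8,15.9994,
Al,13,26.9815,
Ar,18,39.9480,
Ca,20,40.0780,4.0386
Fe,26,55.8450,7.112
I,53,126.9045,33.1694
Ba,56,137.3270,37.4406
Sm,62,150.3600,46.8342
Eu,63,151.9640,48.519
Gd,64,157.2500,50.2391
Tb,65,158.9250,51.9957
Yb,70,173.0500,61.3323
Lu,71,174.9670,63.3138
Ta,73,180.9480,67.4164
W,74,183.8400,69.525
Pt,78,195.0840,78.3948
Au,79,196.9670,80.7249
Bi,83,208.9800,90.5259
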