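label,x,y,z
Fp1,-0.289274,0.950767,-0.111184
Fp2,0.272513,0.955666,-0.111526
Fpz,-0.008810,0.998070,-0.061470
AF7,-0.544023,0.825719,-0.149085
AF3,-0.344927,0.924209,0.163899
AF4,0.341226,0.924557,0.169583
AF8,0.531133,0.833859,-0.150255
F7,-0.760443,0.626168,-0.172165
F5,-0.707559,0.694258,0.131780
F3,-0.545323,0.737454,0.398478
F1,-0.296474,0.760294,0.577977
Fz,-0.007451,0.770973,0.636824
F2,0.295832,0.766969,0.569423
F4,0.539736,0.749430,0.383457
F6,0.706037,0.697423,0.122936
F8,0.753038,0.634313,-0.174871
FT7,-0.922439,0.342257,-0.178793
FC5,-0.890062,0.396716,0.224515
FC3,-0.691041,0.439687,0.573705
FC1,-0.376680,0.453403,0.807798
FC2,0.367175,0.464244,0.806015
FC4,0.687440,0.448392,0.571289
FC6,0.885481,0.407996,0.222400
FT8,0.915545,0.358719,-0.181927
T7,-0.986637,0.002492,-0.162917
C5,-0.957278,0.029127,0.287698
C3,-0.742960,0.051500,0.667352
C1,-0.399840,0.067190,0.914119
Cz,-0.006616,0.073778,0.997253
C2,0.399984,0.072161,0.913677
C4,0.745397,0.060161,0.663900
C6,0.957818,0.040180,0.284554
T8,0.985903,0.014236,-0.166714
TP7,-0.936929,-0.325035,-0.128516
CP5,-0.895430,-0.336695,0.291275
CP3,-0.687442,-0.327539,0.648184
CP1,-0.369212,-0.313754,0.874781
CPz,-0.006509,-0.311830,0.950115
CP2,0.378495,-0.312523,0.871247
CP4,0.694009,-0.321761,0.644067
CP6,0.899722,-0.326568,0.289576
TP8,0.936606,-0.324836,-0.131345
P7,-0.786601,-0.612618,-0.077182
P5,-0.726815,-0.639031,0.251754
P3,-0.555723,-0.643253,0.526686
P1,-0.296353,-0.642485,0.706674
Pz,-0.007003,-0.639995,0.768347
P2,0.304831,-0.634168,0.710570
P4,0.558853,-0.637560,0.530283
P6,0.721903,-0.644342,0.252348
P8,0.782564,-0.617549,-0.078905
PO7,-0.566320,-0.823954,-0.019560
PO3,-0.382749,-0.862617,0.330750
POz,-0.008406,-0.882112,0.470965
PO4,0.367903,-0.870847,0.325996
PO8,0.557204,-0.830127,-0.020315
O1,-0.301460,-0.952607,0.040763
Oz,-0.009348,-0.994924,0.100192
O2,0.287397,-0.956947,0.040685
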