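joint	x_frac	y_frac	z_frac
HipCenter	0	0.53	0
Spine	0	0.65	0
ShoulderCenter	0	0.818	0
Head	0	0.936	0
ShoulderLeft	-0.1295	0.818	0
ElbowLeft	-0.1295	0.65	0
WristLeft	-0.1295	0.5	0
HandLeft	-0.1295	0.46	0
ShoulderRight	0.1295	0.818	0
ElbowRight	0.1295	0.65	0
WristRight	0.1295	0.5	0
HandRight	0.1295	0.46	0
HipLeft	-0.0955	0.52	0
KneeLeft	-0.1295	0.285	0
AnkleLeft	-0.1295	0.039	0
FootLeft	-0.1295	0	0.04
HipRight	0.0955	0.52	0
KneeRight	0.1295	0.285	0
AnkleRight	0.1295	0.039	0
FootRight	0.1295	0	0.04
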