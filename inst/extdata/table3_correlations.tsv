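trait	FN_BMD	LS_BMD	BUA	SOS	NSA	FNL	NN_width	Shaft_width	Shaft_Z
FN_BMD	0.455	0.426	0.280	0.297	-0.080	-0.208	-0.346	0.113	0.499
LS_BMD	0.659	0.634	0.258	0.169	-0.064	-0.195	-0.622	0.327	0.264
BUA	0.435	0.425	0.483	0.744	0.052	-0.254	-0.458	-0.325	0.189
SOS	0.457	0.551	0.975	0.451	-0.102	-0.237	-0.489	-0.437	0.061
NSA	0.046	0.031	-0.037	0.183	0.306	-0.167	-0.446	-0.270	-0.199
FNL	0.240	0.112	0.164	0.159	0.222	0.649	-0.526	-0.790	-0.145
NN_width	-0.193	0.086	0.027	0.037	0.110	0.528	0.947	-1.000	-0.996
Shaft_width	-0.241	-0.151	-0.037	-0.035	0.058	0.660	0.906	0.948	-0.443
Shaft_Z	0.276	0.395	0.183	0.242	0.214	0.575	0.570	0.673	0.677
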