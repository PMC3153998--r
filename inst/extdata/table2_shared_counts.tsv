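trait	FN_BMD	LS_BMD	BUA	SOS	NSA	FNL	NN_width	Shaft_width	Shaft_Z
FN_BMD	5012	489	211	210	35	44	76	48	197
LS_BMD	622	4806	202	205	43	45	47	55	162
BUA	263	245	4437	1791	44	43	38	48	70
SOS	353	293	2017	4779	44	46	43	49	57
NSA	41	51	53	37	4189	36	47	49	45
FNL	43	34	62	57	40	4372	150	200	138
NN_width	90	53	75	60	50	194	4281	515	126
Shaft_width	90	38	66	60	37	207	529	4272	319
Shaft_Z	212	144	64	84	47	138	106	347	4239
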