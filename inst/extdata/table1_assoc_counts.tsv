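trait	n_sig_alpha_0.01	lowest_p
FN_BMD	5012	2.56e-06
LS_BMD	4806	1.45e-05
BUA	4437	5.25e-06
SOS	4779	3.43e-07
NSA	4189	7.98e-07
FNL	4372	5.57e-07
NN_width	4281	4.15e-08
Shaft_width	4272	8.78e-06
Shaft_Z	4239	1.87e-07
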