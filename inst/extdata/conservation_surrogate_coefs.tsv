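term	coef
intercept	3.29068519
row_max	0.20138039
row_spread	-0.53057859
row_sd	0.23647593
focal_max	0.00000000
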