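population	p11	p10	p01	p00
Gumuz	0.71	0	0	0.29
Amhara	0.21	0	0.02	0.77
YRI	0.16	0.01	0.03	0.8
LWK	0.04	0.13	0.19	0.64
MSL	0.13	0.01	0.03	0.84
CEU	0	0	0	1
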