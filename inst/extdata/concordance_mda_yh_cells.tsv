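sc_category	control_category	share	count
HOMref	HOMref	2	1373228.00
HOMref	HETref	1	21871.00
HOMref	HOMmut	0	14.33
HOMmut	HOMmut	2	256682.67
HOMmut	HETref	1	27674.00
HOMmut	HOMref	0	7.33
HOMmut	HOMmut	0	1.67
HOMmut	HETref	0	0.00
HETref	HETref	2	256185.67
HETref	HOMref	1	212.67
HETref	HOMmut	1	326.33
HETref	HETref	1	2.33
HETref	HOMmut	0	0.00
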