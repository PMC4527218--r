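sc_category	control_category	share	count
HOMref	HOMref	2	849057.40
HOMref	HETref	1	10352.40
HOMref	HOMmut	0	45.40
HOMmut	HOMmut	2	266889.00
HOMmut	HETref	1	18507.40
HOMmut	HOMref	0	213.40
HOMmut	HOMmut	0	11.20
HOMmut	HETref	0	4.60
HETref	HETref	2	58948.80
HETref	HOMref	1	12287.20
HETref	HOMmut	1	6860.40
HETref	HETref	1	8.80
HETref	HOMmut	0	0.00
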