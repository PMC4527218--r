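category	control	detected
HOMref	1584649	1373448
HOMmut	270225	257025
HETref	351490	305733
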