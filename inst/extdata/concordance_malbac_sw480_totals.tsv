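category	control	detected
HOMref	1762437	851558
HOMmut	403431	273806
HETref	173098	87822
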