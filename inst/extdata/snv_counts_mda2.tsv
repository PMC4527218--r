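sample	detected_het	fp_het	ado_count	detected_hom	fp_hom	control_het	control_hom
MDA-2_46	777908	5563	390038	1747004	390107	2051282	1598291
MDA-2_47	1807282	6517	14124	1562036	14177	2051282	1598291
MDA-2_66	1651733	6347	55158	1587456	55195	2051282	1598291
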