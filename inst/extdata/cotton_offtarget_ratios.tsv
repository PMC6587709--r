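gene	sgrna	pam_class	hits	sites
AP2	sgRNA1	NGG	0	441
AP2	sgRNA1	NAG	0	57
AP2	sgRNA1	NGA	0	155
AP2	sgRNA2	NGG	0	765
AP2	sgRNA2	NAG	0	55
AP2	sgRNA2	NGA	0	83
MYB44	sgRNA1	NGG	0	683
MYB44	sgRNA1	NAG	0	55
MYB44	sgRNA1	NGA	0	151
MYB44	sgRNA2	NGG	2	182
MYB44	sgRNA2	NAG	0	8
MYB44	sgRNA2	NGA	0	15
ARC	sgRNA1	NGG	2	341
ARC	sgRNA1	NAG	0	66
ARC	sgRNA1	NGA	0	54
ARC	sgRNA2	NGG	0	884
ARC	sgRNA2	NAG	0	169
ARC	sgRNA2	NGA	0	249
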