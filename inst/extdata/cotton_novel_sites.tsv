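gene	sgrna	pam_class	level	n	total
AP2	sgRNA1	NGG	site	4	441
AP2	sgRNA2	NGG	site	7	765
MYB44	sgRNA1	NGG	site	12	683
MYB44	sgRNA2	NGG	site	4	182
ARC	sgRNA1	NGG	site	4	341
ARC	sgRNA2	NGG	site	8	884
AP2	sgRNA1	NGG	pam	0	441
AP2	sgRNA2	NGG	pam	3	765
MYB44	sgRNA1	NGG	pam	1	683
MYB44	sgRNA2	NGG	pam	0	182
ARC	sgRNA1	NGG	pam	0	341
ARC	sgRNA2	NGG	pam	1	884
AP2	sgRNA1	NAG	site	0	57
AP2	sgRNA2	NAG	site	2	55
MYB44	sgRNA1	NAG	site	0	55
MYB44	sgRNA2	NAG	site	1	8
ARC	sgRNA1	NAG	site	0	66
ARC	sgRNA2	NAG	site	3	169
AP2	sgRNA1	NAG	pam	0	57
AP2	sgRNA2	NAG	pam	0	55
MYB44	sgRNA1	NAG	pam	0	55
MYB44	sgRNA2	NAG	pam	0	8
ARC	sgRNA1	NAG	pam	0	66
ARC	sgRNA2	NAG	pam	0	169
AP2	sgRNA1	NGA	site	2	155
AP2	sgRNA2	NGA	site	2	83
MYB44	sgRNA1	NGA	site	3	151
MYB44	sgRNA2	NGA	site	0	15
ARC	sgRNA1	NGA	site	0	54
ARC	sgRNA2	NGA	site	3	249
AP2	sgRNA1	NGA	pam	0	155
AP2	sgRNA2	NGA	pam	0	83
MYB44	sgRNA1	NGA	pam	0	151
MYB44	sgRNA2	NGA	pam	0	15
ARC	sgRNA1	NGA	pam	1	54
ARC	sgRNA2	NGA	pam	0	249
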