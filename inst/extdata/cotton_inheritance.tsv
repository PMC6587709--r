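locus	allele	code	sample	generation	count
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTAAAAGG	no	s1	T0	0
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTTAAAAGG	i1	s1	T0	0
AP2_sgRNA1_D13	ATGGTTGCATCCTG--TAAAAGG	d2	s1	T0	18
AP2_sgRNA1_D13	ATGGTTGCATCCTGC--AAAAGG	d2	s1	T0	23
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTAAAAGG	no	s1	T0	0
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTTAAAAGG	i1	s1	T0	0
AP2_sgRNA1_D12	ATGGTTGCATCCTG--TAAAAGG	d2	s1	T0	7
AP2_sgRNA1_D12	ATGGTTGCATCCTGC--AAAAGG	d2	s1	T0	41
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTAAAAGG	no	s20	T1	0
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTTAAAAGG	i1	s20	T1	0
AP2_sgRNA1_D13	ATGGTTGCATCCTG--TAAAAGG	d2	s20	T1	0
AP2_sgRNA1_D13	ATGGTTGCATCCTGC--AAAAGG	d2	s20	T1	54
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTAAAAGG	no	s20	T1	0
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTTAAAAGG	i1	s20	T1	0
AP2_sgRNA1_D12	ATGGTTGCATCCTG--TAAAAGG	d2	s20	T1	3
AP2_sgRNA1_D12	ATGGTTGCATCCTGC--AAAAGG	d2	s20	T1	27
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTAAAAGG	no	s23	T1	0
AP2_sgRNA1_D13	ATGGTTGCATCCTGCCTTAAAAGG	i1	s23	T1	0
AP2_sgRNA1_D13	ATGGTTGCATCCTG--TAAAAGG	d2	s23	T1	26
AP2_sgRNA1_D13	ATGGTTGCATCCTGC--AAAAGG	d2	s23	T1	11
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTAAAAGG	no	s23	T1	0
AP2_sgRNA1_D12	ATGGTTGCATCCTGCCTTAAAAGG	i1	s23	T1	0
AP2_sgRNA1_D12	ATGGTTGCATCCTG--TAAAAGG	d2	s23	T1	0
AP2_sgRNA1_D12	ATGGTTGCATCCTGC--AAAAGG	d2	s23	T1	31
AP2_sgRNA2_D13	CCTAGCAAAGTCCGATGGTATAA	no	s1	T0	24
AP2_sgRNA2_D13	CCTAGCAAAAGTCCGATGGTATAA	i1	s1	T0	0
AP2_sgRNA2_D13	CCTAGATTAGTCCGATGGTATAA	s3	s1	T0	0
AP2_sgRNA2_D13	CCTAGCA-AGTCCGATGGTATAA	d1	s1	T0	1
AP2_sgRNA2_D13	CCTAGCA--GTCCGATGGTATAA	d2	s1	T0	0
AP2_sgRNA2_D13	CCTAGC---GTCCGATGGTATAA	d3	s1	T0	1
AP2_sgRNA2_A12	CCTAGCAAAGTCCGATGGTATAA	no	s1	T0	22
AP2_sgRNA2_A12	CCTAGCAAAAGTCCGATGGTATAA	i1	s1	T0	0
AP2_sgRNA2_A12	CCTAGATTAGTCCGATGGTATAA	s3	s1	T0	0
AP2_sgRNA2_A12	CCTAGCA-AGTCCGATGGTATAA	d1	s1	T0	13
AP2_sgRNA2_A12	CCTAGCA--GTCCGATGGTATAA	d2	s1	T0	0
AP2_sgRNA2_A12	CCTAGC---GTCCGATGGTATAA	d3	s1	T0	0
AP2_sgRNA2_D13	CCTAGCAAAGTCCGATGGTATAA	no	s20	T1	32
AP2_sgRNA2_D13	CCTAGCAAAAGTCCGATGGTATAA	i1	s20	T1	2
AP2_sgRNA2_D13	CCTAGATTAGTCCGATGGTATAA	s3	s20	T1	0
AP2_sgRNA2_D13	CCTAGCA-AGTCCGATGGTATAA	d1	s20	T1	1
AP2_sgRNA2_D13	CCTAGCA--GTCCGATGGTATAA	d2	s20	T1	0
AP2_sgRNA2_D13	CCTAGC---GTCCGATGGTATAA	d3	s20	T1	0
AP2_sgRNA2_A12	CCTAGCAAAGTCCGATGGTATAA	no	s20	T1	29
AP2_sgRNA2_A12	CCTAGCAAAAGTCCGATGGTATAA	i1	s20	T1	3
AP2_sgRNA2_A12	CCTAGATTAGTCCGATGGTATAA	s3	s20	T1	0
AP2_sgRNA2_A12	CCTAGCA-AGTCCGATGGTATAA	d1	s20	T1	0
AP2_sgRNA2_A12	CCTAGCA--GTCCGATGGTATAA	d2	s20	T1	0
AP2_sgRNA2_A12	CCTAGC---GTCCGATGGTATAA	d3	s20	T1	1
AP2_sgRNA2_D13	CCTAGCAAAGTCCGATGGTATAA	no	s23	T1	0
AP2_sgRNA2_D13	CCTAGCAAAAGTCCGATGGTATAA	i1	s23	T1	0
AP2_sgRNA2_D13	CCTAGATTAGTCCGATGGTATAA	s3	s23	T1	0
AP2_sgRNA2_D13	CCTAGCA-AGTCCGATGGTATAA	d1	s23	T1	21
AP2_sgRNA2_D13	CCTAGCA--GTCCGATGGTATAA	d2	s23	T1	0
AP2_sgRNA2_D13	CCTAGC---GTCCGATGGTATAA	d3	s23	T1	0
AP2_sgRNA2_A12	CCTAGCAAAGTCCGATGGTATAA	no	s23	T1	27
AP2_sgRNA2_A12	CCTAGCAAAAGTCCGATGGTATAA	i1	s23	T1	0
AP2_sgRNA2_A12	CCTAGATTAGTCCGATGGTATAA	s3	s23	T1	0
AP2_sgRNA2_A12	CCTAGCA-AGTCCGATGGTATAA	d1	s23	T1	0
AP2_sgRNA2_A12	CCTAGCA--GTCCGATGGTATAA	d2	s23	T1	0
AP2_sgRNA2_A12	CCTAGC---GTCCGATGGTATAA	d3	s23	T1	0
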