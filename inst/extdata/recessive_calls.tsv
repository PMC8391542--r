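sample_id	type	chrom	start	end	size	bayes_factor	reads_ratio	exon_annotation
CS047	deletion	1	148261458	148262366	908	5.27	0.04	NBPF20_98-99
CS048	deletion	9	35061	35519	458	6.51	0.0	FAM138C_1-2
CS004	deletion	17	57656834	57657240	406	5.38	0.0	DHX40_9-10
CS035	deletion	17	57656834	57657240	406	4.91	0.0	DHX40_9-10
CS043	deletion	17	57656834	57657240	406	6.0	0.0	DHX40_9-10
CS050	deletion	17	57656834	57657240	406	7.23	0.0	DHX40_9-10
CS053	deletion	17	57656834	57657240	406	7.02	0.0	DHX40_9-10
CS057	deletion	17	57656834	57657240	406	6.29	0.0	DHX40_9-10
CS010	deletion	17	57657000	57657107	107	4.2	0.52	DHX40_9
CS020	deletion	17	57656900	57657400	500	5.1	0.49	DHX40_9-10
CS030	deletion	17	57656000	57657200	1200	6.3	0.51	DHX40_8-10
CS040	deletion	17	57655000	57657354	2354	5.7	0.48	DHX40_7-10
CS071F	deletion	17	57656834	57657240	406	5.0	0.5	DHX40_9-10
CS064	deletion	5	1000000	1000500	500	5.9	0.02	ZNF992_1-3
CS036F	deletion	5	1000000	1000500	500	6.1	0.03	ZNF992_1-3
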