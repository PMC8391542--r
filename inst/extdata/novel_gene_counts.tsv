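gene	type	chrom	size_min	size_max	patient_count	control_count
LRRC40	deletion	1	30080	383938	4	0
SCN7A	deletion	2	544	11914	4	0
MME	deletion	3	279	55232	4	0
NAE1	deletion	16	6724	71803	4	0
TBX6	deletion	16	525296	723210	4	0
DHX40	deletion	17	107	2354	10	1
GMCL1	deletion	2	11694	24032	5	1
MYSM1	deletion	1	190	10053	4	1
RASA2	deletion	3	2892	100149	4	1
NSMAF	deletion	8	203	12325	4	1
MNS1	deletion	15	52610	323156	4	1
PHKB	deletion	16	7697	99254	4	1
SPO11	deletion	20	730	33608	4	1
ABCA6	duplication	17	560	13580	4	1
ZZZAA	deletion	4	500	900	3	0
ZZZBB	deletion	6	1000	2000	5	2
ZZZCC	deletion	7	800	1600	4	0
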