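FAM033	CS033	0	0	2	2
FAM053	CS053	0	0	2	2
FAM064	CS064	0	0	2	2
FAM059	CS059	0	0	2	2
FAM078	CS078	0	0	2	2
FAM081	CS081	0	0	2	2
FAM004	CS004	0	0	2	2
FAM035	CS035	0	0	2	2
FAM010	CS010	0	0	2	2
FAM020	CS020	0	0	2	2
FAM030	CS030	0	0	2	2
FAM040	CS040	0	0	2	2
FAM018	CS018	CS018F	CS018M	2	2
FAM018	CS018F	0	0	1	1
FAM018	CS018M	0	0	2	1
FAM036	CS036	CS036F	CS036M	2	2
FAM036	CS036F	0	0	1	1
FAM036	CS036M	0	0	2	1
FAM071	CS071	CS071F	CS071M	2	2
FAM071	CS071F	0	0	1	1
FAM071	CS071M	0	0	2	1
FAM047	CS047	CS047F	CS047M	2	2
FAM047	CS047F	0	0	1	1
FAM047	CS047M	0	0	2	1
FAM057	CS057	CS057F	CS057M	2	2
FAM057	CS057F	0	0	1	1
FAM057	CS057M	0	0	2	1
FAM043	CS043	CS043F	CS043M	2	2
FAM043	CS043F	0	0	1	1
FAM043	CS043M	0	0	2	1
FAM043	CS043S1	CS043F	CS043M	1	1
FAM050	CS050	CS050F	CS050M	2	2
FAM050	CS050F	0	0	1	1
FAM050	CS050M	0	0	2	1
FAM050	CS050S1	CS050F	CS050M	1	1
FAM048	CS048	CS048F	CS048M	2	2
FAM048	CS048F	0	0	1	1
FAM048	CS048M	0	0	2	1
FAM048	CS048S1	CS048F	CS048M	1	1
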