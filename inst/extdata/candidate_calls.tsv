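sample_id	type	chrom	start	end	size	bayes_factor	reads_ratio	exon_annotation
CS033	deletion	1	120611949	120612020	71	4.62	0.657	NOTCH2_1
CS043	deletion	1	120539621	120612020	72399	8.46	0.722	NOTCH2_1-4
CS018	deletion	21	41452080	41452267	187	4.65	0.429	DSCAM_25
CS036	deletion	21	41452080	41452267	187	6.02	0.415	DSCAM_25
CS050	deletion	21	41452080	41452267	187	5.8	0.468	DSCAM_25
CS053	deletion	21	41452080	41452267	187	5.45	0.494	DSCAM_25
CS064	deletion	21	41452080	41452267	187	6.1	0.463	DSCAM_25
CS048	deletion	8	51503440	51571223	67783	6.37	0.43	SNTG1_13-15
CS059	deletion	16	29674601	30199897	525296	644	0.555	SPN_2,AC009133.19_2-3,QPRT_1-4,C16orf54_2,ZG16_2-4,KIF22_1-13,MAZ_1-5,PRRT2_2-3,PAGR1_1-3,CTD-2574D22.6_1-2,MVP_2-15,CDIPT_6-2,SEZ6L2_16-1,ASPHD1_1-3,KCTD13_6-1,TMEM219_1-4,TAOK2_2-16,HIRIP3_7-1,INO80E_1-7,DOC2A_11-2,C16orf92_2-3,FAM57B_5-1,ALDOA_8-16,PPP4C_2-9,TBX6_9-2,YPEL3_4-1,GDPD3_10-1,MAPK3_8-1,CORO1A_2-3,CORO1A_4-10
CS071	deletion	16	29495011	30218221	723210	754	0.572	NPIPL3_3-1,SPN_2,AC009133.19_2-3,QPRT_1-4,C16orf54_2,ZG16_3-4,KIF22_2-12,MAZ_1-5,PRRT2_2-3,PAGR1_1-3,CTD-2574D22.6_1-2,MVP_2-15,CDIPT_6-2,SEZ6L2_16-1,ASPHD1_1-3,KCTD13_6-1,TMEM219_1-4,TAOK2_2-16,HIRIP3_7-2,INO80E_1-7,DOC2A_11-2,C16orf92_2-3,FAM57B_5-1,ALDOA_8-16,PPP4C_2-9,TBX6_9-2,YPEL3_4-1,GDPD3_10-1,MAPK3_8-1,CORO1A_2-11,BOLA2B_3-1,SLX1A_1-5,SULT1A3_3-9,RP11-347C12.3_5-2
CS078	deletion	16	29498516	30199897	701381	690	0.578	NPIPL3_1,SPN_2,AC009133.19_2-3,QPRT_1-4,C16orf54_2,ZG16_3-4,KIF22_2-12,MAZ_1-5,PRRT2_2-3,PAGR1_1-3,CTD-2574D22.6_1-2,MVP_2-15,CDIPT_6-2,SEZ6L2_16-1,ASPHD1_1-3,KCTD13_6-1,TMEM219_1-4,TAOK2_2-16,HIRIP3_7-2,INO80E_1-7,DOC2A_11-2,C16orf92_2-3,FAM57B_5-1,ALDOA_8-16,PPP4C_2-9,TBX6_9-2,YPEL3_4-1,GDPD3_10-1,MAPK3_8-1,CORO1A_2-10
CS081	deletion	16	29498516	30199897	701381	645	0.558	NPIPL3_1,SPN_2,AC009133.19_2-3,QPRT_1-4,C16orf54_2,ZG16_3-4,KIF22_2-12,MAZ_1-5,PRRT2_2-3,PAGR1_1-3,CTD-2574D22.6_1-2,MVP_2-15,CDIPT_6-2,SEZ6L2_16-1,ASPHD1_1-3,KCTD13_6-1,TMEM219_1-4,TAOK2_2-16,HIRIP3_7-2,INO80E_1-7,DOC2A_11-2,C16orf92_2-3,FAM57B_5-1,ALDOA_8-16,PPP4C_2-9,TBX6_9-2,YPEL3_4-1,GDPD3_10-1,MAPK3_8-1,CORO1A_2-10
CS050F	deletion	21	41452080	41452267	187	5.5	0.47	DSCAM_25
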