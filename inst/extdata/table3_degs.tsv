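module	color	comparison	gene	hub	direction
M1	turquoise	stage1_vs_2	hsa-mir-3189	0	down
M1	turquoise	stage1_vs_2	hsa-let-7D	0	down
M1	turquoise	stage1_vs_2	hsa-mir-25	0	down
M1	turquoise	stage1_vs_2	LINC00342	0	down
M1	turquoise	stage1_vs_2	LINC00685	0	down
M1	turquoise	stage1_vs_2	hsa-mir-186	0	down
M1	turquoise	stage1_vs_2	hsa-mir-3682	0	down
M1	turquoise	stage1_vs_2	CLUHP3	0	down
M3	brown	stage1_vs_2	FAM83A	0	up
M3	brown	stage1_vs_2	MYBL2	1	up
M3	brown	stage1_vs_2	KIF4A	1	up
M3	brown	stage1_vs_2	STC1	0	up
M3	brown	stage1_vs_2	RRM2	1	up
M3	brown	stage1_vs_2	DEPDC1	1	up
M3	brown	stage1_vs_2	ANLN	1	up
M6	red	stage1_vs_2	SCGB3A2	1	down
M6	red	stage1_vs_2	CYP4B1	1	down
M6	red	stage1_vs_2	CRYM	0	down
M6	red	stage1_vs_2	PIGR	0	down
M6	red	stage1_vs_2	WIF1	0	down
M6	red	stage1_vs_2	C4BPA	0	down
M6	red	stage1_vs_2	CYP2B7P	1	down
M6	red	stage1_vs_2	SFTPB	1	down
M6	red	stage1_vs_2	VSIG2	0	down
M6	red	stage1_vs_2	PRSS12	0	down
M6	red	stage1_vs_2	PLA2G10	0	down
M6	red	stage1_vs_2	CACNA2D2	1	down
M6	red	stage1_vs_2	ELAPOR1	0	down
M6	red	stage1_vs_2	DUOXA1	0	down
M6	red	stage1_vs_2	ZBTB7C	0	down
M6	red	stage1_vs_2	ALPL	0	down
M6	red	stage1_vs_2	CLIC6	0	down
M6	red	stage1_vs_2	HLF	1	down
M6	red	stage1_vs_2	FAM189A2	1	down
M6	red	stage1_vs_2	CYP4X1	0	down
M6	red	stage1_vs_2	DUOX1	0	down
M6	red	stage1_vs_2	CFAP221	1	down
M6	red	stage1_vs_2	C5orf49	0	down
M6	red	stage1_vs_2	CEBPA-DT	0	down
M6	red	stage1_vs_2	B3GNT8	1	down
M6	red	stage1_vs_2	ENTPD3	0	down
M6	red	stage1_vs_2	SCUBE2	0	down
M6	red	stage1_vs_2	OLFM1	0	down
M6	red	stage1_vs_2	ERICH2	0	down
M6	red	stage1_vs_2	WFDC2	0	down
M6	red	stage1_vs_2	PDZD2	0	down
M9	magenta	stage1_vs_2	FDCSP	0	down
M9	magenta	stage1_vs_2	MS4A1	0	down
M9	magenta	stage1_vs_2	PTGDS	0	down
M9	magenta	stage1_vs_2	RAB37	0	down
M1	turquoise	stage1_vs_rest	hsa-mir-3189	0	down
M1	turquoise	stage1_vs_rest	NPIPB15	0	down
M1	turquoise	stage1_vs_rest	ZDHHC11B	0	down
M1	turquoise	stage1_vs_rest	hsa-let-7D	0	down
M1	turquoise	stage1_vs_rest	LINC00342	0	down
M1	turquoise	stage1_vs_rest	CLUHP3	0	down
M1	turquoise	stage1_vs_rest	LINC00685	0	down
M1	turquoise	stage1_vs_rest	hsa-mir-3682	0	down
M3	brown	stage1_vs_rest	FAM83A	0	up
M3	brown	stage1_vs_rest	STC1	0	up
M3	brown	stage1_vs_rest	ANLN	1	up
M3	brown	stage1_vs_rest	ELOVL6	0	up
M3	brown	stage1_vs_rest	LYPD3	0	up
M3	brown	stage1_vs_rest	RRM2	1	up
M3	brown	stage1_vs_rest	SLC2A1	0	up
M3	brown	stage1_vs_rest	MYBL2	1	up
M3	brown	stage1_vs_rest	KIF4A	1	up
M3	brown	stage1_vs_rest	CEP55	1	up
M3	brown	stage1_vs_rest	TNNT1	0	up
M3	brown	stage1_vs_rest	EXO1	1	up
M3	brown	stage1_vs_rest	TUBB3	0	up
M3	brown	stage1_vs_rest	HMMR	1	up
M3	brown	stage1_vs_rest	DEPDC1	1	up
M3	brown	stage1_vs_rest	MKI67	0	up
M3	brown	stage1_vs_rest	FOXM1	1	up
M6	red	stage1_vs_rest	PGC	0	down
M6	red	stage1_vs_rest	SFTPC	0	down
M6	red	stage1_vs_rest	SCGB3A2	1	down
M6	red	stage1_vs_rest	CYP4B1	1	down
M6	red	stage1_vs_rest	CRYM	0	down
M6	red	stage1_vs_rest	CYP2B7P	1	down
M6	red	stage1_vs_rest	AQP5	0	down
M6	red	stage1_vs_rest	SCGB3A1	0	down
M6	red	stage1_vs_rest	PIGR	0	down
M6	red	stage1_vs_rest	C4BPA	0	down
M6	red	stage1_vs_rest	SFTPB	0	down
M6	red	stage1_vs_rest	C16orf89	1	down
M6	red	stage1_vs_rest	CLDN18	0	down
M6	red	stage1_vs_rest	SFTPA2	0	down
M6	red	stage1_vs_rest	DMBT1	0	down
M6	red	stage1_vs_rest	CACNA2D2	1	down
M6	red	stage1_vs_rest	WIF1	0	down
M6	red	stage1_vs_rest	PRSS12	0	down
M6	red	stage1_vs_rest	GGTLC1	1	down
M6	red	stage1_vs_rest	SFTPA1	0	down
M6	red	stage1_vs_rest	VSIG2	0	down
M6	red	stage1_vs_rest	AQP4	0	down
M6	red	stage1_vs_rest	SCGB1A1	0	down
M6	red	stage1_vs_rest	TMEM130	0	down
M6	red	stage1_vs_rest	HLF	1	down
M6	red	stage1_vs_rest	LRRK2-DT	1	down
M6	red	stage1_vs_rest	SFTPD	0	down
M6	red	stage1_vs_rest	C8orf34-AS1	0	down
M6	red	stage1_vs_rest	ATP13A4	1	down
M6	red	stage1_vs_rest	AGER	0	down
M6	red	stage1_vs_rest	FAM189A2	0	down
M6	red	stage1_vs_rest	ALPL	0	down
M6	red	stage1_vs_rest	ELAPOR1	0	down
M6	red	stage1_vs_rest	SUSD2	1	down
M6	red	stage1_vs_rest	CLIC6	0	down
M6	red	stage1_vs_rest	RNASE1	0	down
M6	red	stage1_vs_rest	CFAP221	1	down
M6	red	stage1_vs_rest	CYP4X1	0	down
M6	red	stage1_vs_rest	PLA2G10	0	down
M6	red	stage1_vs_rest	NAPSA	1	down
M6	red	stage1_vs_rest	PEBP4	1	down
M6	red	stage1_vs_rest	SFTA3	1	down
M6	red	stage1_vs_rest	CEBPA-DT	0	down
M6	red	stage1_vs_rest	GGT6	0	down
M6	red	stage1_vs_rest	HSD17B6	0	down
M6	red	stage1_vs_rest	LMO3	0	down
M6	red	stage1_vs_rest	IRX2	0	down
M6	red	stage1_vs_rest	TDRD10	0	down
M6	red	stage1_vs_rest	B3GNT8	1	down
M6	red	stage1_vs_rest	SCTR	1	down
M6	red	stage1_vs_rest	SPINK5	0	down
M6	red	stage1_vs_rest	ESYT3	1	down
M6	red	stage1_vs_rest	PLA2G1B	0	down
M6	red	stage1_vs_rest	HABP2	0	down
M6	red	stage1_vs_rest	SCUBE2	0	down
M6	red	stage1_vs_rest	C5orf49	0	down
M6	red	stage1_vs_rest	CFTR	0	down
M6	red	stage1_vs_rest	WFDC2	0	down
M6	red	stage1_vs_rest	GFRA3	0	down
M6	red	stage1_vs_rest	DAPK2	1	down
M6	red	stage1_vs_rest	MFSD4A	0	down
M6	red	stage1_vs_rest	ZBTB7C	0	down
M6	red	stage1_vs_rest	CPAMD8	1	down
M6	red	stage1_vs_rest	FCGBP	0	down
M6	red	stage1_vs_rest	ZNF750	0	down
M6	red	stage1_vs_rest	KLF15	0	down
M6	red	stage1_vs_rest	SUSD4	0	down
M9	magenta	stage1_vs_rest	FDCSP	0	down
M9	magenta	stage1_vs_rest	MS4A1	0	down
M9	magenta	stage1_vs_rest	PTGDS	0	down
M9	magenta	stage1_vs_rest	hsa-mir-8071-1	0	down
M16	lightcyan	stage1_vs_rest	CD19	0	NA
M16	lightcyan	stage1_vs_rest	CD79A	0	NA
M16	lightcyan	stage1_vs_rest	CR2	0	NA
M16	lightcyan	stage1_vs_rest	IGHJ3P	0	NA
M16	lightcyan	stage1_vs_rest	IGHV3-63	0	NA
M16	lightcyan	stage1_vs_rest	IGLV10-54	0	NA
M16	lightcyan	stage1_vs_rest	IGHD	0	NA
M16	lightcyan	stage1_vs_rest	IGHM	0	NA
M16	lightcyan	stage1_vs_rest	IGHJ1	0	NA
M16	lightcyan	stage1_vs_rest	IGHV3-47	0	NA
M16	lightcyan	stage1_vs_rest	IGLC3	0	NA
M16	lightcyan	stage1_vs_rest	IGKV6D-21	0	NA
M16	lightcyan	stage1_vs_rest	IGKV1D-16	0	NA
M16	lightcyan	stage1_vs_rest	IGLV1-44	0	NA
M16	lightcyan	stage1_vs_rest	IGLC7	0	NA
M16	lightcyan	stage1_vs_rest	IGLV2-18	0	NA
M16	lightcyan	stage1_vs_rest	IGHV3-13	0	NA
M16	lightcyan	stage1_vs_rest	IGKV1-8	0	NA
M16	lightcyan	stage1_vs_rest	IGHV3-64	0	NA
M16	lightcyan	stage1_vs_rest	IGLV3-9	0	NA
M16	lightcyan	stage1_vs_rest	IGLV1-36	0	NA
M16	lightcyan	stage1_vs_rest	IGLV3-27	0	NA
M16	lightcyan	stage1_vs_rest	IGLV8-61	0	NA
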