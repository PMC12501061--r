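name	side	gene
eight_gene	num	ATP6V0E1
eight_gene	num	SVBP
eight_gene	num	HSDL1
eight_gene	num	UBTD1
eight_gene	den	GNPNAT1
eight_gene	den	XRCC2
eight_gene	den	TFAP2A
eight_gene	den	PPP1R13L
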