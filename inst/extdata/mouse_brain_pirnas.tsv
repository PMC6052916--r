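id	reads	alternative	sequence	miwi_ip_reads	chr17_cluster
DQ541777	16130	RNY1	GGCTGGTCCGAAGGTAGTGAGTTATCTCAA	1	FALSE
DQ705026	6257	snoRNA 2	CTGAAATGAAGAGAATACTCTTGCTGATC	0	FALSE
DQ555094	3439	rRNA 28S	TGGGGGGCCCAAGTCCTTCTGATCGAGGCCCA	0	FALSE
DQ719597	2459	snoRNA 85	GGTCGATGATGAGAGCTTTGTTCTGAGC	0	FALSE
DQ689086	1514	snoRNA 27	TGCAATGATGTCATCTTACTACTGAAA	0	FALSE
DQ540285	1433	rRNA 18S	ATCGATGTGGTGCTCCGGAGTTCTCTTCGGGC	0	TRUE
DQ540981	1360	rRNA 28S	CGGGCCGCCGGTGAAATACCACTACTCTCA	0	FALSE
DQ720186	849	miR-3102-3p	AGAGCACCCCATTGGCTACCCAC	0	FALSE
DQ555093	775	rRNA 28S	TGGGGGGCCCAAGTCCTTCTGATCGAGGC	1	FALSE
DQ540862	639	snoRNA Z12	CCGGGTGATGCGAATCGTAATCTGAGCCGA	0	FALSE
DQ540284	635	rRNA 18S	ATCGATGTGGTGCTCCGGAGTTCTCTTCGGG	0	TRUE
DQ541506	580	rRNA 18S	GATCGATGTGGTGCTCCGGAGTTCTCTT	0	TRUE
DQ539915	304	CDS: MT_CO1	AACATTTCCTGGGCCTTTCAGGAATACCACGA	0	FALSE
DQ540861	252	snoRNA 104	CCGGGTGATGCGAATCGTAATCTGAGC	0	FALSE
DQ715526	207	snoRNA 17	CACCAAGATGAGTGGTGCAAATCTGATC	0	FALSE
DQ543676	182	rRNA 18S	TCGATGTGGTGCTCCGGAGTTCTCTTCGGGC	0	TRUE
DQ722288	175	snoRNA D81	TTACTTGATGATAGTAAAAGATCTGATG	0	FALSE
DQ551351	168	CDS: Fth1	TGCTTCAACAGTGCTTGAACGGAACCCGGT	1	FALSE
DQ550765	118	snRNA U12	TGCGGGATGCCTGGGTGACGCGATCTGCCCG	0	FALSE
DQ708131	115	snoRNA 25	TATCTGTGAGGATAAGTAACTCTGAGG	0	FALSE
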