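id	reported_length	detected_in	rpm	alternative	start_type	sequence
PIR54042	27	40	2295.39	RNAY4	67	CCCCCCACTGCTAAATTTGACTGGCT
PIR2888	30	40	1684.62	RNAY1	1	GGCTGGTCCGAAGGTAGTGAGTTATCTCA
PIR58596	31	40	1604.31	MT_rRNA 16S	1	GCTAAACCTAGCCCCAAACCCACTCCACCC
PIR43376	32	40	327.78	MT_tRNA-Val	1	CAGAGTGTAGCTTAACACAAAGCACCCAACT
PIR57581	31	39	312.29	MT_tRNA-Ser	1	GAGAAAGCTCACAAGAACTGCTAACTCATG
PIR54043	26	40	59.41	RNAY4	67	CCCCCCACTGCTAAATTTGACTGGT
PIR59288	32	33	57.53	tRNA-AlaCGC	1	GGGGGGTGTAGCTCAGTGGTAGAGCGCGTGC
PIR40304	32	40	44.88	MT_tRNA-His	32	TGAATCTGACAACAGAGGCTTACGACCCCTT
PIR41574	31	40	41.07	piRNACluster	Chr5	TGAGATGCGGGAGCTCCGGCGCACACACTC
PIR227919	21	40	34.69	MT_tRNA-Met	1	AGTAAGGTCAGCTAATTAAG
PIR75448	31	40	33.04	tRNA-IleAAT	1	GGCCGGTTAGCTCAGTAGGTTAGAGCTTGG
PIR45809	31	34	28.77	MT_tRNA-Ser	29	TGCCCCCATGTCTAACAACATGGCTTTCTC
PIR57849	32	20	26.67	CDS: MT_CO2	Antisense	GAGGGCGTGATCATGAAAGGTGATAAGCTCT
PIR57322	27	36	20.9	CDS: PPP1R3E	Sense, exon	GACAACAACGGCGGCCGTGACTATGC
PIR59786	31	30	18.06	MT_tRNA-Phe	3'END	GTTTAGACGGGCTCACATCACCCCATAAAC
PIR37665	28	23	17.91	piRNACluster	Chr11	TCCTGTATTTGCCGAATTGTGGTGTTT
PIR52755	30	35	17.16	CDS: SPATA31D1	Sense, exon	TGTGCAGAATATTGGTCGAGTTATAAGAG
PIR55478	30	18	17.05	CDS: C6orf89	Sense, exon	TTCCAGTGCCGAAGACATTGTCAGTCTGT
PIR33872	31	33	16.74	CDS: VKORC1L1	Sense, exon	TCAAGGCTAAATCTGCTCATGTCGCCACTG
PIR31112	30	34	15.99	MT_tRNA-Met	3'END	AAATGTTGGTTATACCCTTCCCGTACTAC
PIR49916	28	31	15.85	piRNACluster	Chr6	TGGGAGTGAAATCAGTGTTTAGGACTA
PIR59752	31	33	13.49	MT_tRNA-Leu	1	GTTAAGATGGCAGAGCCCGGTAATCGCATA
PIR59421	32	27	12.25	rRNA_28S	4549	GGTTAGTTTTACCCTACTGATGATGTGTTGT
PIR51124	27	20	11.73	MT_tRNA-Glu	41	TGGTCGTGGTTGTAGTCCGTGCGAGA
PIR1340	31	33	10.51	MT_tRNA-Met	5	AGGTCAGCTAATTAAGCTATCGGGCCCATA
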