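id	sum_rpm_cancer	alternative	sequence
FR072386	38911332	miR-let-7a-1	TGAGGTAGTAGGTTGTATAGTTTTAGGGTC
FR182987	3814379	miR-532-5p	CATGCCTTGAGTGTAGGACCGT
FR074386	1093572	snoRNA 98	ATGCAGTGTGGAACACAATGAACTGAAC
FR140858	1177195	miR-106b	TAAAGTGCTGACAGTGCAGATAGTGGTCCTC
FR114004	823121	snoRNA 1B	TTTCTGTGTGGAATTTGAATATCTGAAA
FR075316	744575	snoRNA 82	ACCTGATGTTACATTGTAGTGTGCTGATG
FR132879	635984	snoRNA 58	ACTGCAGTGATGACTTTCTTAGGACACCTTTG
FR064000	407046	snoRNA 58B	CTGCGATGATGGCATTTCTTAGGACACCTTTG
FR163199	301387	snoRNA 138	CATGATACTGTAAACGCTTTCTGATG
FR043670	268790	MT_tRNA-Glu	TGGTCGTGGTTGTAGTCCGTGCGAGAA
FR091055	185930	miR-744-5p	TGCGGGGCTAGGGCTAACAGCA
FR190827	201282	snoRNA 6	AGGGGCTGAATGAAAATGGCCTTTCTGAAC
FR090905	168436	MT_rRNA 16S	GCTAAACCTAGCCCCAAACCCACTCCA
FR016773	172895	snoRNA 42B	ACTTGTGATGTCTTCAAAGGAACCACTGATG
FR136216	162693	snoRNA 62	AGGGAGATGAAGAGGACAGTGACTGAGAGAC
FR004819	123249	snoRNA 114-1	GACGGTGAATACAGGTCTGGAAGTCTGAGGT
FR103462	96101	snoRNA 98	AAATGCAGTGTGGAACACAATGAACTGAAC
FR089006	95184	tRNA-Gly	AGCGCCGCTGGTGTAGTGGTATCATGCAAG
FR026913	74640	snoRNA 89	GAGGAATGATGACAAGAAAAGGCCGAA
FR019019	81678	snoRNA 107	GTTCATGATGACACAGGACCTTGTCTGAAC
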