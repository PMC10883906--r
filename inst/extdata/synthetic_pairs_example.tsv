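sgrna	dna	label
GCAACCAACAGAGAGAACGCNGG	GCAACCAACAGAGAGAAAGCAGG	0
AAGTAGTAGACTCACATGAANGG	AAGTAGTATACTGACACGAACGA	0
AGTTAAGCATGGGACCAGCGNGG	AGTTAAGCATGTGTGCAGGGGGC	0
CCATGTGACCTGTACTGCCCNGG	CCATGTGACCTGTACTGGCCAGG	0
CTCTCAACGGATACGAGTCGNGG	CTCTTGGCGAATACGAGTCGTGG	1
AACTATGCAGAGTACGTAACNGG	AACTATACAGAGTACGTAACCGG	1
AAAGGGTGACCAAGCGATTTNGG	GAAGGGTGACCAAGCGATTGGGT	0
TCGGACGCGTCGCAGCGCCTNGG	TCGGACGCGTCGCAGCGCCTGGG	1
GAACCATAGGGGGGCTGGCCNGG	GAAACACAGCGGGGCAGGCCAGG	0
CGATAGATTGCCAGCGCAGCNGG	CGAGAGTTTGACACCGCAGCCGG	1
TGTGACTGAAATCACCCTTTNGG	CGTGGCTAATATCACCCTTGCTG	0
CTCAGTTATGCTGATCGGTGNGG	CTCAGTTATGCTGATCGGTGGGG	1
AAGTGCGAATATGTATCCAGNGG	AAGTGCGAATAGGTATCGAGAGG	0
TCGTGTGCGCCATGCCCCCTNGG	TCGTGTACGCCACTCCCCGGGGG	0
AACGTCGGCCTGACAGGGATNGG	AACGTCGGCCTGACAGGGACAGG	0
TTACATCGTGAGGGTAGGCGNGG	TTACATCGTGAGGGTAGGCGGGT	0
AATTACAATGACAGCATTACNGG	AATTAAAATGACAGCGTTACGGG	0
ATAACAAGCGTCCCACCGCTNGG	ATAACAAGCATCGAACCGCTAGG	1
GTAGGCTGAAATATCTCGGTNGG	GGACGCTGAAGTTTCTGGATGGG	0
TTCTATGTGCATAATTATCGNGG	TTCTATGTGCCTCATAATCAGCG	0
ACTACATTAGGCACGCCTCANGG	TCCACATGAGGCACGCGCAATGG	0
TACTTTCTAATCTCTGGTTCNGG	TACGTAATAATCTTTGTTTCAAG	0
GCCTCTACATCTGGCGCATTNGG	GCCTCCACACCTGGCGCATAAGG	0
TGGCCTCTGATACTTTACTCNGG	CGGCCTCTGATACTTAACTCTGG	0
AAGATGTATGGATAGATTCGNGG	AAGAACTATGCATAGACTCGCGG	0
CGGAGTATTAGTTCGCCCGCNGG	TGGAGTATTAGTTCGCCCGAAGG	0
AGTGCCAGGATATAACTCAGNGG	GCTGTCAGGATATGACTCAGGGT	0
ATCGTACACTATCGCGTGTCNGG	ATCGTTCACTATCCCGTGTAAGG	0
ATTTCTTCAATTTGTGCGGCNGG	AGGTCTTCAATTTGTGCGGCTGT	0
AAGAAAATCTTGTCTGGTAANGG	AAGAAAATCTTGTCTGGTCATGG	0
AAAAAACGCTGTCGACACTTNGG	AAAAAACGCTGTCGACACTTCCG	0
CGGATCTTGCACTCAACCCGNGG	CTGATCTTGCACTGAACCCGAGG	1
CTAACCCCGGCGTTTCCCTANGG	CTAACCCCGGCGTTTCACTAAGG	0
ATGGAAACGACCATCACCGCNGG	TGGGCAACGACCATCACCGAAGG	0
CGGAACTTTAGCAGGCGCCGNGG	CGGAACTTTAGCAGGTGCCGTGG	0
AAGTCGCAACGGTTGTGCAANGG	AACTCGCAATGGTTGTGCAAGCG	0
TCACTTGCGGTGGCCGACTANGG	TCACTTGCGGTTGCCTAGTAAGT	0
CTCATGCTCTGCTCCAGTCTNGG	CACATGCTCAGCTCCGGTCTCAA	0
AAATCTACGGCGAGGGAGGCNGG	AAATCTACGGCGAGGGAGGGTGG	0
CCCAAGCTAATAGCCTATTTNGG	CCCAAGCGAATAGCCTATTAGTT	0
CCAAGTCCTGATATACACCGNGG	CTAAGTCCGGATATTCAGAGAGG	0
GTCTGGGGTGGTTTACTTTGNGG	GTCTTAGGTGGTTTACATTGTGG	0
TCACAGGATTTCAAATCGTGNGG	TCACAGGATTTCAAATCGTGAGG	1
ACCTAAACAGCGATGGTAGANGG	ACCTAAACAGCGATGGTCGAGGC	0
TCTAGAAGTGAAGTGCTCATNGG	TCTAGAAGTCAAGTGCTCATCGA	0
ATTCGAGATGTAACGCTTGCNGG	ATTCCAGATGTTACGCCTTCCGG	0
CCGGGTGAAGACTCTAACTCNGG	CCGGGTGAAGACTCGAACTCCGG	1
ATTATACAATAAGCGGTAACNGG	ATGTTACATTATGGGGTACCCGG	0
GAGACAGTAACAAAACGTGGNGG	GCGACAGTATAAAAACGTCGATG	0
TATCTTCTTTTTTGTACGTTNGG	TATCTTCCTTTTTCTAATAAGGG	0
CGGCCAGTAACGAGGAACTCNGG	CCGCGAGTAGCGAGGAATTGTGG	0
GGAGATATCGTGAAATTACANGG	GGAGAGGTCGTAGACCTACAAGG	0
GTATGGAGGTTTGTCCTAATNGG	GTGTAGAGATTTGTACTAGATGG	0
TGGAATACTGCTCTATTTAANGG	TGGAATACTGCTCTATTTAACGG	1
TAAGCAAGATTCACGATGTTNGG	TAAGCAAGATTCACGATTTTTGG	0
CTCAGGGCGCCCTGTGAGCTNGG	CTCTGGGGACCCTGTGCTCTTGA	0
GATTACGAGCCAAGTCTCGGNGG	GATTACGGGCCATATCTCGGCCA	0
ACACGAACACTTCCTGCCGGNGG	ACATGGACACTTCCTGACGAGGG	0
AACGAGAAAGCCATCCTCGGNGG	AACAAGAACGCCATCATCGCAAG	0
TGTCTTACTTCCATTATCAANGG	TCTTTTACTTCCATTAACAATTG	0
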