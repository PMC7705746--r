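element_id	ltr5_seq	ltr3_seq
ltr_00001	GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACACTTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCT	GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACACTTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCT
ltr_00002	TCAGTGTAGCATGGGTGGTTTACAGCTGGTCCTCAAACAGAGCGAATGAATCGCAGGTGCCCTCCGACTATTTGGGGCATGTTTAGTCTTGTAGAATCCACTAGTGTGGTAACCGTACAGTACATTGGGGATCAGTGCAGTTAGCATGCCGAACAGCGCGACGGACAATCTCGCTCTCAAGGACATCTCAAAGTTTCGGT	TAAGTGTAGCATGGGTGGTTTACAGCTGGTCCTCAAACAGAGCGATTGAATTGCAGGTGCCCTCCGACTATTTGGGACATGTTTAGTCTTGTAGAATCCACTAGTGTGGTAACCGTACAGTACATTGGGGATCAGTGCAGATAGCATGCCGAACAGCGCGACGGACAATCTCGCTCTCAAGGACATCTCAAAGTTTCGGT
ltr_00003	GCGCCGTAGGGAAATGACTTGTGACGCCGAGTCGCCGAGGGCTAGGCGAAGGACAAAACCCACGATGGGCTCCCTTTGTCAGTAACTGAAAGGATGATTCGTTCGTTTGTTCTTCGCGGTCCTAGTTTCTCGACACGCCCTTGCTTCACTGGTGTTGCAATATACTGAATGACATCTATCGCCCCTCCCCCACATGCGCG	GCGCCGTAGGGAAATGACTTGTGACGCCGAGTCGCCGAGGGCTAGGCGAAGGACAAAACCCACGATGGGCCTCCTCTGTCAGTAACTAAAAGGTGGATTCGTTCGTTTGTTCTTCGCGGCCCTATCTTCTCGACACGCCCTTGCTTCGCTGGTGTTGCAATAAACTGAATGACATCTATCGCCCCTCCCCCACATGCGCG
ltr_00004	GAACACCGGAGCATCCAACGATAAGAGACAGGCATACTTATTCTCACTACTATGTAGCTGAAGAGTGCTATACAACCATCGTGGGCTGTGTCACCCGAGGCATTAGGCTATATTTTTATTGTGAGCAACGCGCAGAAGTGCCCAAATCGTTCGACTGTATGACCGAATCTAGTCATCACTGGATGCTACATGCTTTAGGT	GAACACCGGAGCATCCAACGATAAGAGACAGGGATACCTATTCTCACTAGTATGTAGCTGAAGAGTGCTATACAATCATCGTGGGCTGTGTCTCCAGAGGGATTAGGCTATATTTTTATTGTGAGCAACGCGCAGAAGTGCCCAAATCGTTCGACTGTATGACCGAATCTAGTCATCACTGGTTGCTACAAGCTTTAGGT
ltr_00005	GCCACGACGCCCCGGAAGTTCGGGGGGTAGGGTACACTCCTCTGCAGGCTGCAGCGCTACTTAGCGAAAGTGACCGAGAGGGTATTTCCTGTGTGTTTCTCAAACGACTCATGCCGGGATTGTTCAGGTTTCGCCACCAAACTCAACATCTGAGGGTTCGGATGGGTTACGCCAAAACAGCCATGCTTTGTAGCGTAGTG	GCCACGATGCCCCGGAAGTTCGGGGGATATGGTACGCCCCTCTGCAAGCTGCAGCGCTACTGAGCGAAAGTGACCGAGACGGTACTTCCTGCGTGTTTCTCAAACCACTCGGGCCGGGATTGTTCAGGTTTCGCCACTAAACTCCACATCTGAGGGTCCGCATGGGTTACTCCAAAAGAGCCATGCTCTGTAGCGTAGTG
ltr_00006	ACTTTTCTTGGTATTCAACCCAGAACATGATGGACCGGTCGGCTACCTGAATCGACACGCGGATTAACCCGGAGCGTCTTCTCGGCCGGGGGATAGTAGAGATTGGGGGAGGTGGCATTAATTCTTACCGACATGACATGGTTATATTACTTGGTGTCCCTGGACATTGCTGCGGGATGACCGCCAAAATCTATCTGGTC	ACTTTTCTTGGTATTCAATCCAGAACATGAAGGACGGGTCGGCTCCCTGATTCGACACACGGATTAACCCGGAGCGTCTTCTCGGCCGGGGGATAGGAGAGATTGGGGGGGGTGGCATTAATTCTTACCGACATGACATGGTTATATTAATGGGTGTTCCTGGACATAGCTGCCGCATGACCGCCAAAATCTATCTGGTC
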