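>pBR_synthetic
CGTGTCCATGGATATTGGCTGCCAGGGCATACGTATCCTGTCACACATCACATCTGAAGCGGGGGACGAT
GTATGGGTCGAGCCGGGCGTGGCCGTCCCGTGTTGGTCATGATCCGCAGGCAGTTGACCGCCACTGGGCC
CTAGTGAAGGACTAGTTACTTCGGGCTCATAAGGACGCAGCACGGCGCGATTACACGACCGCGGCGCCGC
GGGTTATAACGCGCCGTGATCATTATGCTCCTCTCCTGCGAAACGACGCAACATCCGGGTGACCCCCCGC
GGGGGCCCGTATCCACGGTACCTGGGCCCACGTGATACCCCCCCTCATAACCGGGGGACCCCCCCTCTAT
ATTCAAACGGTTCTAGGGTTGGAATAAGGCTTCCCGACTTACTGGTTCTGTGACCGGGGTCCCCCGCCGC
CTTAACCGTATGTGAAAGGCGGGACAAAGAAGATCCCGACTATCGCACGCGCACAGCCATTCCCTCGGAG
AGGTCGGGTT
>Hygro_synthetic
TGTGCGAGAGATAGTATGAAATGTCGCGGGGACAACCATGTTGGCGCGGAGGGCGGAGAAACGTCTGCAT
ATAGGGGCAGTCGGCCGTTCCGAGCGTCGGAGAGCACGCGTCGGAGCCGCCGCGTCATAAATGGCGGGTA
GCTCGGGAAAACCTGAGAGGGGCTCGGTACGTCGGACAGGGGCCGCCGATGACGCCGGTCAGCGCCTTGT
GGGTAAATGGCGGTTTTTCCACCGCGTCAATGTGGGCCGAGGTGTACCCAGGGGCCATGGAGCGCTTGGG
GTGAGAACTTCCATAGACAACGTACCAATGATATGCGCAACGGTTAGTCGTACAGTAGCCCCATCGGCAG
TATCGCCAACACTATTACATTGCCCATCCCCTGAGGTGAGCGAAGATCCTGGCAAAGGGGGGGTGGATCG
TCGAGCCATGGACAGGAAGGGTAGCACGGTCCGCCTCCCATTTGCGTTGCATCTCTTGGCGACCGAGCAT
TAGGCAAGAG
>SNRPN_synthetic
CCGGCCGCCGGCTAACCTGGCGGGGAAAGACATCGAGATCATTAGCCGTGTAGCAGAGGCTGTTTGTAGC
CGTAAGCGTGTGATGTGGGAGCACGCCGTGGGCCAATAATGGGGTGAGGTAAAATCCGGATCGCGGCTCC
CAGGCGAAGCCGAAAACTGCATAGTTATCTTGGTCGGGGGTCCCAACCGGCTCTATCACGAAAAGACCTC
AAGGCGCAAGTAAAAGGTGTTTAAGTTCATCCGTTCTAGTCCACTACCGTAAGAGCCAAAGAACAGGATT
ACCTGCGGTGCGTAACATTA
>TIMELESS_synthetic
GTTATCGCAGTGGCACTTGTAAGCTTGGGGGAACCTCAGTGTGTGCCTACCTCTATCTGGAGCTTGGATG
GCTGTTACCTGCAGTGAATACACCAGTATAAGTAGGTCACGTACCCCTGGCTGTTGTGCCAGTAAGGCAA
ATGAGGACGGTTTGGAAGTAGCACACAGCTTGTACGGGACAGCCCCGGTTGCAGCGATGTTTCAAGATGT
AGTCTTGGGGACTTGTGGTTCCAAATAAGCCGACCCTGGAATGGCCAATGTGTTGAGGAGGATCATGACA
GCCATGGAAACTGATGTAGCACGCTGCAGATGATAGTGCGCATGTCCCTTTAAATTGGGAGTGTATGCCA
ACTCAGTCCTGACTGTTTAAGGGTGCCGGAACCCCACTCAAGGCTCGTGTGGGCAGGAGACTGTGCCTCA
TGCTTTGAGGACTGACATAGTCTCTTGCCCCCAGAACTACCATCCCTTCCTAGGACGGTATGAAGGCAAT
TGTTGGTTGA
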