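>SYNSPIKE01
GTTTCCCCGCCCCAGGACTTTGGCTTTTACATTTCAAATTCGCAAACATGACTAGGCTTTCGTAGGTCGG
TTGACCTCCAGCGGGCCATGTTTGTAACGGTGTCGCGATGGATTTATCGAGTGTCGTGCTCTCGCTACAG
ACGAACCGCAGGTAAGTCTTTCGGCTGAGTCCGACGGATTAGATTTGCGGATTAAGGAGCGACCAATTGC
TACTGAAAGAAACGGTCCCTTAGGAGATTCTAATATAGTAGTCAGTGGACGCAGCTTGCTCGATTCTTTC
TGTGTATGTATGCTCCCGTTATTTTGCTGGCC
>SYNSPIKE02
GCGCGATATCGCAATAATGGCTGTCCCACACGGAGACACTAGCATATACCCGGTTCAATGTTTGATCTCC
GACTCGCTTACTGCGAGGCCTAGTAAGGGTGCCAACCCAGCATCCGGCGGTGTATAGAACACTCTCCAGC
CGTTCCAACTGCTCAACTTACAGGAGTGGAAGCGATTAGTGGATTCGCGGATACTAAGCCACCCGGACAA
CCCACAGTCAGTCACACGTAATGTACGGCATGAATTGTCCCACGGTGTTACAATAAGCGGGGTCCGGGTA
CCGCAAACGAATGTTATAAGCGTGGATGAATGGTGTACCCAGTTCAATATGCCAACGT
>SYNSPIKE03
TCGAGACCTGACTTCGTATCCCACTGGAGATTTTATGGCGATGGTAGCAAAGGTAGGTAAGTACACAATT
GGGAGGCCTCTTGACGATTCCACAAAGTAATATTAACAGTAGCCGCACAGTTTGAGGTTCTCCCAACTAG
GTGACGCACCGAGAGACAGACCTCCAGTTGGTAGCCTAGGATTTGCCGACTCCGTTACACAGTGGCCTGG
CTGTCAGAGTAGGGCACGTGCCCAACTAATATGATACTATCACCTCCAACACTTAAGCTACTATATCCTA
GGGCTGAAACCGGCGTGTGGTGACCGATTTGTCTGATCACGATCGAGGGGTTCTGACTGGCGAAGGTGGT
ATCCACTGTGA
>SYNSPIKE04
CCTCGATGTCACACAAGGTGGGCATTATCCTCATCTTTGTCCTATTCCCACTCGACGGTAATATTTACGA
GGGCGTCTTTACGATATGTCTATAGCTCACTTTAGTCAGGGAAGTGAGGCTTGACCTAGATCGCAAATTA
TTGCTCGTCAAACTGCCTGAAATCCTCCCTCCTTGCGGGCCAGTAAGAAATCGACTTGCTACCTTCTTTG
CAGCGCCGCTTCCGTTTCGAAGTGCTGAAGCATCGCGTGGGGCATTTCATTCGTTATGCATATCTACGCC
TCCTCGCCAAATGGCGCTTCTAAGAGTCTCTCCAAGTTGGGCGCCGTCTGGACAGGAACAGGCCTTGCTT
AACACCATACGGAAGGAGGGCACAGCATAGAGACTGG
>SYNSPIKE05
GCGGGAGGGAGAGTCTTCCCAGCAACGTATATAGTTTTTATATAGCACTTCAATCACGTGGTTAATTAGG
TTGCCGCTTAGTAATATGATATAAACTCGTGTCTGTACAATGGCACTTTGGCGTCCCCCGCATTTAGGTA
ACAACAACGCAACTAGGGCCCGAATTATACGAATAAGGTTTGCCTCCCAGAATGTTTTGCCCCGTGGCGT
CTGATGTTACCCCTCTACATGGTATCGGGGGTCAAGACGAGCGTAGCGCCGTATACGACAACGGTGGCCA
TCATGGAACTCAGCTCGGGAGTTTTAGCGGGCCCTGTCATCGAACAGATGACTGCGATAGCGACCGGGTT
CGAGTATAGTTTTGGCGAAAACTATTACCCGCTATAAAAATTCGAACAGTACTTAATTCCCCCT
>SYNSPIKE06
CATGCAGGTAATTATGTAATACTACCAGGGTTTTAATGCCTTTCACGAATCTTAGACAAGATTGATGACA
ACTCCACTCGTCCGGTGATCGAGCCTGTTGGAAGCAGCGCAAGTGAGATCCCACCTGAAAGATAGGTTTC
TCCGGGTTTAGAAACAGGTGTGTGTACCACAGCAATACCCGTTGGGAGCTTGGTGGGTTGGACAAGGAAG
CGCCGGACTAGACTCTAGGCAAATCCATACAAGTCTCAGATACCCCTTTCTAATCACTTGAATTAGGCTC
CGCTGGTAACAGAATCACCAGGCGCGACGTACTAGGATGGTATCTTAGCGAGAAATGTACTTACTGAACT
ACAGAGTTTTTACGGGTACCACGTAACCTGTGAACCCCACTGGGGGTGGCTAGCTGATACTTACTTCACA
TTAGGTTTCTCAGGACATTGCTCATA
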