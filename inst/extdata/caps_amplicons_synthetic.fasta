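>C_type_synthetic_502bp
ACCGGTCTGGTCACGCGCCTATGAATAGGAATAAGGGCGAAATCAAAGGCTGTCCTGGAGGAAACCAGGC
CGTAGCCCAGACACTTTCGGTGAAAAGTCCGACAGCCAGGCAACCCGGTAGGGTCCCTTTATAAATCTCT
TCGCGAATTGTCACTAAGTTTGCTCTTAAGTGTGTTATCCATGATGGAGCGATTGATTCGCTATGAGCGT
AAACTTTATGAAGGACGAATAGTAAAAGACTAAGCAGGGCCAAATCCATGAACCCTGTCCCCCACCATTC
CACAATTCCCCATCGCATCTCGTCTAAGCCCGGGCCACCACGTGTTGAAGCTATTCTGTCAAATTAGTCT
GTACCGGGCGAACTAGGGACTATTGAATGCCTTTCGACACTACATTTCGCATCGACTGTCTATACATATT
GAGAGCCGCCAGTCTAAATCCGCCGGACAATGGCCATTCGTGCGATTAATAACTTGTAATTCAAACTGAG
AGGTAGACAATA
>T_type_synthetic_502bp
ACCGGTCTGGTCACGCGCCTATGAATAGGAATAAGGGCGAAATCAAAGGCTGTCCTGGAGGAAACCAGGC
CGTAGCCCAGACACTTTCGGTGAAAAGTCCGACAGCCAGGCAACCCGGTAGGGTCCCTTTATAAATCTCT
TCGCGAATTGTCACTAAGTTTGCTCTTAAGTGTGTTATCCATGATGGAGCGATTGATTCGCTATGAGCGT
AAACTTTATGAAGGACGAATAGTAAAAGACTAAGCAGGGCCAAATCCATGAACCCTGTCCCCCACCATTC
CACAATTCCCCATCGCATCTCGTCTAAGCCCGGGCCACCACGTGTTGAAGCTATTCTGTCAAATTAGTCT
GTATCGGGCGAACTAGGGACTATTGAATGCCTTTCGACACTACATTTCGCATCGACTGTCTATACATATT
GAGAGCCGCCAGTCTAAATCCGCCGGACAATGGCCATTCGTGCGATTAATAACTTGTAATTCAAACTGAG
AGGTAGACAATA
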