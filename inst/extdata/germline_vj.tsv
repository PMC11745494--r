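gene	segment	sequence	junction_offset
IGHV9-1*01	V	ATCTGTACGGAAGCCCCATGTGCGTACCAC	12
IGHV9-2*01	V	GAATTTTTTGGGTATAAATGTGCGAGTTCA	12
IGHV9-3*01	V	CCGACCAATCGGTCCGTCTGTGCGGTCGTC	12
IGHV9-4*01	V	GTTCCTTAGGACCGATTGTGTGCGGTTAAT	12
IGHV9-5*01	V	AGCGAAGTAACAAGAGATTGTGCGCGTCTT	12
IGHV9-6*01	V	GCGACCAGAAACGCCCAATGTGCGGGCGAC	12
IGHV9-7*01	V	CATTTCATCCGTAAAACGTGTGCGAGACAC	12
IGHV9-8*01	V	GTGCACCGATTTCGCCGTTGTGCGGAGAGC	12
IGHV9-9*01	V	GACTGAATGGAATTATTCTGTGCGCCGCTT	12
IGHV9-10*01	V	TGTATGGTAATGTAGCTATGTGCGGCCTTT	12
IGHJ9-1*01	J	GATTGTCCTTGGTACCATGATGTTGGTCGA	12
IGHJ9-2*01	J	GGTAAAGCTTGGTCGCATGTTGACTATTTT	12
IGHJ9-3*01	J	TGCTTTGCGTGGGGGAACCGAGAGGATGGT	12
IGHJ9-4*01	J	CGTTATTCATGGGTTACACGAAGGAGATTC	12
IGHJ9-5*01	J	CTGGCTTCATGGACAATCACGCAGGTAGCA	12
IGHJ9-6*01	J	GGTAAGCTTTGGACGTCAGCTGCTTGCACA	12
IGHJ9-7*01	J	TCGACAGTGTGGAGGGCACCCCGTTTCGGG	12
IGHJ9-8*01	J	CTTAAGCAGTGGACCCGAATGTTGTAGATA	12
IGHJ9-9*01	J	TACCCACCTTGGATGCCGTACACCGGGCCG	12
IGHJ9-10*01	J	CGTTGTTCATGGGATTGTTATACACGGTCG	12
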