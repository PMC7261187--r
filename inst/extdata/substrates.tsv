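name	sequence	lesion_position	lesion_type	scored_sites	polya_length
unmodified	TCGATCGAGTCGGGCCCTTGACAGTTTCTAAGGGATTGCGGTCACGGATTCCGAGCCCAACCAAATTTGTGGGGTAAGCG	44	unmodified	45	30
uracilA	ATTCGTAATCTCCATTATGGCTAGTCGTAGGCGTTCGTCTGACACAGCCTAGGTCGTGTGAAGCACTGTGTGTTTCATGC	44	U_A	45	30
uracilG	ACTCGTCAAGACGTCGTTACGAGTCACACGGCATGACCGGAGTTGGACCGATCGCTTTGTTGGTACTGGCCTCAGTTTCG	44	U_G	45	30
riboG	AAAGCTCTGGCCCGCTTCGGGCAGATGTCCATATAAGGCTCTGCGAGGTCGCCTGCTGATGCCAGAACGCGCGACCAGCC	44	riboG_C	44	30
abasicG	CGGAACTGAGTAGGTCGGCGATGGGGGCACACAGAGTCGCGCCATCGCCGGGCCAATATCCTACCCAAATTATGTGTGGG	44	abasic_G	45,46	30
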