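variant	sequence
PRE	TCGAGTGCCGAGCGGGGTGGGCCGGATCAG
M1	TCGAGTGCCGAGCGGGGTGGTACCGATCAG
M2	TCGAGTGCCGAGCGCTGTGGGCCGGATCAG
M3	TCGAGTCGCGAGCGGGGTGGGCCGGATCAG
M4	TCGAGTGCCGAGCGGGGTGGGCCTGTACAG
M5	TCCATGGCCGAGCGGGGTGGGCCGGATCAG
M6	TCGAGTGCCGATCGGGGTGGGCCGGATCAG
M7	TCGAGTCCGGAGCGGGGTGGGCCGGATCAG
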