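variant	sequence
wildtype	TCGGGTGCCGAGCGGGGTGGGCCGGATCAG
rs201592736	TCGGGTGCCGAGCGAGGTGGGCCGGATCAG
rs200621906	TCGGGTGCCGAGCGGGGTGGGCCAGATCAG
both	TCGGGTGCCGAGCGAGGTGGGCCAGATCAG
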