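factor	site	mw
AP2	GGGGTGGGCCG	32;40;47;48;49;50;51;52
BTEB1	GAGCGG	
BTEB1	GGCCGG	
BTEB2	GAGCGG	25
BTEB2	GGCCGG	25
GATA1	GGGTGGGC	43;51
GATA1	CCGGATCAGc	43;51
GATA2	CCGGATCAGc	50
Msx1	GAGCGG	31
Msx1	GGCCGG	31
Pax4a	GGGGTGGGCCGG	38
PuF	GGGTGGG	17
R	GTGCCGAGCGGGGTGGGC	67
SP1	GGGTGG	81;95;105
SP1	TGGGCCGGATCAGctg	81;95;105
SP1	GAGCGG	81;95;105
SP1	GGCCGG	81;95;105
TCERG1	CGAGTG	122;124
TCERG1	CGAGCG	122;124
USF1	GGATCAGctgactc	34;43;55
USF2	GGATCAGctgactc	37;44
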