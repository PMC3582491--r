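cell_line	assay	F	psi
NB	band_I	9.79	1.65
NB	band_II	26.54	2.72
NB	ELISA	21.20	2.43
PC12	band_I	4.23	1.09
PC12	band_II	58.96	4.05
PC12	ELISA	29.96	2.89
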