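cell_line	assay	variant	mean	g
NB	band_I	PRE	0.00	0.00
NB	band_I	M1	1.81	3.24
NB	band_I	M2	-1.33	-2.39
NB	band_I	M3	0.60	1.07
NB	band_I	M4	0.40	0.72
NB	band_I	M5	-0.28	-0.51
NB	band_I	M6	0.27	0.48
NB	band_I	M7	1.00	1.78
NB	band_II	PRE	0.00	0.00
NB	band_II	M1	-1.76	-4.86
NB	band_II	M2	-0.43	-1.18
NB	band_II	M3	0.79	2.19
NB	band_II	M4	-1.62	-4.48
NB	band_II	M5	0.07	0.19
NB	band_II	M6	-0.61	-1.68
NB	band_II	M7	0.87	2.41
NB	ELISA	PRE	1.00	0.00
NB	ELISA	M1	0.37	-3.12
NB	ELISA	M2	0.81	-0.91
NB	ELISA	M3	1.69	3.40
NB	ELISA	M4	0.89	-0.52
NB	ELISA	M5	0.34	-3.24
NB	ELISA	M6	0.16	-4.14
NB	ELISA	M7	1.04	0.18
PC12	band_I	PRE	0.00	0.00
PC12	band_I	M1	1.25	1.77
PC12	band_I	M2	-0.91	-1.43
PC12	band_I	M3	0.56	0.84
PC12	band_I	M4	0.61	0.91
PC12	band_I	M5	0.16	0.25
PC12	band_I	M6	0.27	0.41
PC12	band_I	M7	1.46	2.04
PC12	band_II	PRE	0.00	0.00
PC12	band_II	M1	-1.38	-5.56
PC12	band_II	M2	-0.14	-0.56
PC12	band_II	M3	1.20	4.82
PC12	band_II	M4	-1.04	-4.20
PC12	band_II	M5	0.30	1.23
PC12	band_II	M6	-0.25	-1.01
PC12	band_II	M7	1.58	6.36
PC12	ELISA	PRE	1.00	0.00
PC12	ELISA	M1	0.39	-6.84
PC12	ELISA	M2	0.67	-2.05
PC12	ELISA	M3	0.83	-0.80
PC12	ELISA	M4	0.45	-5.33
PC12	ELISA	M5	0.43	-5.69
PC12	ELISA	M6	0.43	-5.68
PC12	ELISA	M7	1.03	0.12
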