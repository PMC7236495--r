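alphabet	code	formula	mw	charge
protein	G	C2H5NO2	75.067	0
protein	A	C3H7NO2	89.094	0
protein	V	C5H11NO2	117.148	0
protein	L	C6H13NO2	131.175	0
protein	I	C6H13NO2	131.175	0
protein	P	C5H9NO2	115.132	0
protein	F	C9H11NO2	165.192	0
protein	W	C11H12N2O2	204.229	0
protein	M	C5H11NO2S	149.215	0
protein	S	C3H7NO3	105.093	0
protein	T	C4H9NO3	119.12	0
protein	C	C3H7NO2S	121.161	0
protein	Y	C9H11NO3	181.191	0
protein	N	C4H8N2O3	132.119	0
protein	Q	C5H10N2O3	146.146	0
protein	D	C4H7NO4	133.103	0
protein	E	C5H9NO4	147.13	0
protein	K	C6H14N2O2	146.19	0
protein	R	C6H14N4O2	174.204	0
protein	H	C6H9N3O2	155.157	0
protein	U	C3H7NO2Se	168.054	0
protein	pS	C3H8NO6P	185.072	0
protein	pT	C4H10NO6P	199.099	0
protein	pY	C9H12NO6P	261.17	0
protein	HYP	C5H9NO3	131.131	0
protein	ACE	C2H4O2	60.052	0
dna	A	C10H14N5O6P	331.225	0
dna	C	C9H14N3O7P	307.199	0
dna	G	C10H14N5O7P	347.224	0
dna	T	C10H15N2O8P	322.21	0
dna	m6A	C11H16N5O6P	345.252	0
dna	m5C	C10H16N3O7P	321.226	0
rna	A	C10H14N5O7P	347.224	0
rna	C	C9H14N3O8P	323.198	0
rna	G	C10H14N5O8P	363.223	0
rna	U	C9H13N2O9P	324.182	0
rna	PSI	C9H13N2O9P	324.182	0
rna	m7G	C11H17N5O8P	378.258	1
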