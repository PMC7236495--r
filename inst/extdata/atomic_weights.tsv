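symbol	number	weight
H	1	1.008
He	2	4.003
Li	3	6.941
Be	4	9.012
B	5	10.812
C	6	12.011
N	7	14.007
O	8	15.999
F	9	18.998
Ne	10	20.18
Na	11	22.99
Mg	12	24.305
Al	13	26.982
Si	14	28.086
P	15	30.974
S	16	32.067
Cl	17	35.453
Ar	18	39.948
K	19	39.098
Ca	20	40.078
Sc	21	44.956
Ti	22	47.867
V	23	50.944
Cr	24	51.996
Mn	25	54.938
Fe	26	55.845
Co	27	58.933
Ni	28	58.693
Cu	29	63.546
Zn	30	65.39
Ga	31	69.723
Ge	32	72.61
As	33	74.922
Se	34	78.96
Br	35	79.904
Kr	36	83.8
Rb	37	85.468
Sr	38	87.62
Y	39	88.906
Zr	40	91.224
Nb	41	92.906
Mo	42	95.94
Tc	43	98.0
Ru	44	101.07
Rh	45	102.906
Pd	46	106.42
Ag	47	107.868
Cd	48	112.412
In	49	114.818
Sn	50	118.711
Sb	51	121.76
Te	52	127.6
I	53	126.904
Xe	54	131.29
Cs	55	132.905
Ba	56	137.328
La	57	138.906
Ce	58	140.116
Pr	59	140.908
Nd	60	144.24
Pm	61	145.0
Sm	62	150.36
Eu	63	151.964
Gd	64	157.25
Tb	65	158.925
Dy	66	162.5
Ho	67	164.93
Er	68	167.26
Tm	69	168.934
Yb	70	173.04
Lu	71	174.967
Hf	72	178.49
Ta	73	180.948
W	74	183.84
Re	75	186.207
Os	76	190.23
Ir	77	192.217
Pt	78	195.078
Au	79	196.967
Hg	80	200.59
Tl	81	204.383
Pb	82	207.2
Bi	83	208.98
Po	84	209.0
At	85	210.0
Rn	86	222.0
Fr	87	223.0
Ra	88	226.0
Ac	89	227.0
Th	90	232.038
Pa	91	231.036
U	92	238.029
Np	93	237.0
Pu	94	244.0
Am	95	243.0
Cm	96	247.0
Bk	97	247.0
Cf	98	251.0
Es	99	252.0
Fm	100	257.0
Md	101	258.0
No	102	259.0
Lr	103	262.0
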