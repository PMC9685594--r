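residue	F1	F2	F3	F4	F5	F6
A	-0.59	-1.3	-0.73	1.57	-0.15	-0.22
C	-0.85	-0.33	-0.23	0.16	-1.02	0.33
D	-0.88	1	-0.43	-0.45	0.34	-1.15
E	-0.81	0.72	0.39	-0.35	1.04	-1.07
F	1.39	-0.27	0.41	0.35	-0.68	0.42
G	-0.92	-1.79	-1.74	0.81	0.34	0.48
H	0.44	0.6	0.07	-1.04	0.56	1.07
I	1.34	-0.89	-0.29	0.16	-0.54	-0.05
K	-0.68	1	0.5	-0.68	1.06	0.38
L	1.22	-0.83	-0.26	0.54	-0.09	-0.33
M	1.12	-0.26	-0.51	-0.49	-0.47	0.64
N	-0.92	0.66	-0.33	-0.52	0.09	-0.81
P	-0.17	-0.12	-1.81	-1.35	-0.51	1.69
Q	-0.76	0.69	0.19	-0.42	0.62	-0.56
R	-0.69	1.52	0.74	-0.71	0.45	0.44
S	-0.71	-0.46	-0.79	0.17	0.12	-0.65
T	-0.41	-0.48	-0.4	0.37	-0.34	-0.59
V	1.09	-1.07	-0.32	0.54	-0.29	-0.35
W	1.6	0.84	1.68	0.09	-0.65	0.69
Y	1	0.52	1.23	-0.39	-0.32	0.11
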