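residue	ProtFP1	ProtFP2	ProtFP3	ProtFP4	ProtFP5	ProtFP6	ProtFP7	ProtFP8
A	-3.49	0.5	-2.52	1.04	0.23	0.68	-0.94	0.28
C	-1.28	-2.74	0.26	-1.06	-3.42	1.64	1.04	-0.35
D	2.49	-1.57	-1.7	-1.62	0.72	-0.65	0.43	1.11
E	3.02	-0.21	-0.87	-1.5	1.42	-0.32	1.16	-0.95
F	-3.03	2.82	1.55	-0.27	-0.55	-0.64	-0.1	0.68
G	0.67	-3.37	-3.7	1.45	0.52	-0.38	0.23	-0.32
H	1.72	0.91	0.26	-0.48	-1.01	2.02	-1.6	-0.35
I	-4.17	0.25	1.11	1.23	0.12	-0.96	-0.85	-0.45
K	3.21	0.75	-0.29	1.1	-1.42	-1.67	-0.9	-0.07
L	-3.93	0.54	0.84	1.06	0.48	-1.01	0.52	0.26
M	-2.74	0.76	0.67	-0.3	1.6	1.01	1.52	1.05
N	2.28	-0.81	-1.15	-1.15	0.3	0.88	0.22	1
P	0.65	-1.54	-0.35	-3.05	-1.12	-0.86	1	0.22
Q	2.31	0.36	-0.45	-0.71	0.68	0.61	1.2	-1.12
R	3.52	1.5	-0.4	2.09	0.85	0.67	-0.78	0.22
S	1.19	-2.01	-1.57	-0.26	-0.35	0.02	0.09	-1.07
T	0.74	-1.4	-0.1	0.27	-0.23	0.3	-1.55	-0.48
V	-3.79	-0.85	0.98	1.36	-0.27	-0.51	-0.75	-0.34
W	-1.41	4.04	1.49	-1.27	0.69	-0.34	-0.61	-1.13
Y	-0.96	2.87	0.66	-0.8	-1.26	-0.39	0.67	1.81
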