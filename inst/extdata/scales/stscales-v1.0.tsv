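residue	ST1	ST2	ST3	ST4	ST5	ST6	ST7	ST8
A	-1.55	-0.79	-0.63	0.24	-0.46	-2.23	0.28	1.22
C	-1.28	-0.54	0.51	-0.89	-0.62	-1.3	0.06	1.6
D	0.58	-0.99	-1.5	-1.25	0.55	-0.11	-0.9	-1
E	0.61	-0.4	-0.71	-1.37	1.06	0.01	0.33	-0.37
F	0.1	0.71	1.35	1.25	0.88	1.05	0.52	-0.17
G	-1.84	-1.77	-1.26	0.86	0.51	-1.72	0.34	0.86
H	0.37	0.55	0.09	-0.17	0.12	0.67	-1.52	0.47
I	-0.77	0.67	0.98	1.08	-0.39	0.26	0.26	-0.33
K	1.09	0.12	-0.25	0.46	-0.73	-0.4	1.16	0.48
L	-0.74	0.72	0.9	1.02	-0.71	0.16	0.61	0.2
M	-0.6	0.77	0.46	0.27	1.39	0.54	0.1	0.2
N	0.33	-0.89	-0.82	-0.86	0.18	0.37	-0.29	-0.61
P	-0.83	-1.33	-0.88	-1.04	-1.9	0.75	-0.6	-0.5
Q	0.58	-0.11	-0.02	-0.85	0.54	0.44	0.84	-0.71
R	1.55	0.84	-0.38	0.92	-0.77	0.57	0.52	0.54
S	-0.56	-1	-0.87	-0.49	0.06	-0.79	-0.46	0.21
T	-0.4	-0.7	-0.27	-0.25	-0.37	-0.57	-0.63	0.09
V	-0.93	0.18	0.53	1	-0.79	-0.41	0.11	0.03
W	1.04	2.1	1.42	0.39	0.17	0.82	0.29	-0.61
Y	0.48	1.23	0.8	0.07	-0.34	0.46	-0.88	-0.19
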