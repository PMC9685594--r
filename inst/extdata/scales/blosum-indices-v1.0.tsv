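residue	BLOSUM1	BLOSUM2	BLOSUM3	BLOSUM4	BLOSUM5	BLOSUM6	BLOSUM7	BLOSUM8	BLOSUM9	BLOSUM10
A	0.08	-0.13	-0.44	0	0.35	-0.2	0.07	0.09	-0.16	0.04
C	0.48	0.38	-0.06	-0.31	-0.29	0.21	-0.36	0.09	0.17	-0.09
D	-0.67	-0.28	0.26	-0.12	0.18	0.31	0.03	-0.22	0.12	0.14
E	-0.64	-0.11	0.12	0.21	0.26	-0.07	-0.18	0.13	-0.1	-0.06
F	0.6	0.26	0.31	0.22	-0.01	-0.17	0.12	-0.05	-0.21	0.08
G	-0.33	-0.63	-0.31	-0.36	-0.2	0.11	0.21	0.13	0.06	-0.02
H	-0.25	0.31	-0.01	-0.18	0.06	0.3	0.28	0.26	-0.07	-0.19
I	0.61	-0.06	0.28	0.21	0.07	0.24	-0.1	-0.07	0.18	0.05
K	-0.58	0.12	-0.04	0.32	-0.1	-0.16	0.22	-0.12	0.14	0
L	0.54	-0.04	0.25	0.18	0.15	0.06	-0.05	0.13	-0.12	-0.16
M	0.44	0.11	0.18	0.08	0.32	0.11	0.19	-0.26	0.06	0.16
N	-0.52	-0.2	0.09	-0.3	0.1	-0.16	-0.27	0.1	-0.09	0.09
P	-0.36	-0.49	0.11	0.34	-0.37	-0.15	-0.4	-0.15	-0.1	0.04
Q	-0.47	0.13	-0.03	0.21	0.19	-0.07	0.26	0.25	0.2	0.12
R	-0.51	0.27	-0.08	0.27	-0.13	0.25	-0.11	0.1	-0.1	0.15
S	-0.26	-0.27	-0.23	-0.19	0.13	-0.1	0.05	-0.31	0.1	-0.05
T	-0.1	-0.24	-0.15	0.02	-0.03	0.1	0.08	0.16	0.26	0.12
V	0.56	-0.19	0.26	0.26	-0.05	-0.02	0.06	0.14	0.02	-0.1
W	0.54	0.53	0.25	-0.21	-0.29	-0.27	-0.06	0.05	0.12	-0.11
Y	0.31	0.42	0.14	-0.17	-0.09	-0.29	0.02	-0.18	-0.19	0.06
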