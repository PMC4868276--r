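aa	kd_hydropathy	hw_hydrophilicity	grantham_polarity	grantham_volume	cf_helix	cf_sheet	cf_turn	fp_hydrophobicity	zimmerman_pi	residue_mass
A	1.8	-0.5	8.1	31	1.42	0.83	0.66	0.31	6.00	89.09
C	2.5	-1.0	5.5	55	0.70	1.19	1.19	1.54	5.07	121.15
D	-3.5	3.0	13.0	54	1.01	0.54	1.46	-0.77	2.77	133.10
E	-3.5	3.0	12.3	83	1.51	0.37	0.74	-0.64	3.22	147.13
F	2.8	-2.5	5.2	132	1.13	1.38	0.60	1.79	5.48	165.19
G	-0.4	0.0	9.0	3	0.57	0.75	1.56	0.00	5.97	75.07
H	-3.2	-0.5	10.4	96	1.00	0.87	0.95	0.13	7.59	155.16
I	4.5	-1.8	5.2	111	1.08	1.60	0.47	1.80	6.02	131.17
K	-3.9	3.0	11.3	119	1.16	0.74	1.01	-0.99	9.74	146.19
L	3.8	-1.8	4.9	111	1.21	1.30	0.59	1.70	5.98	131.17
M	1.9	-1.3	5.7	105	1.45	1.05	0.60	1.23	5.74	149.21
N	-3.5	0.2	11.6	56	0.67	0.89	1.56	-0.60	5.41	132.12
P	-1.6	0.0	8.0	32.5	0.57	0.55	1.52	0.72	6.30	115.13
Q	-3.5	0.2	10.5	85	1.11	1.10	0.98	-0.22	5.65	146.15
R	-4.5	3.0	10.5	124	0.98	0.93	0.95	-1.01	10.76	174.20
S	-0.8	0.3	9.2	32	0.77	0.75	1.43	-0.04	5.68	105.09
T	-0.7	-0.4	8.6	61	0.83	1.19	0.96	0.26	5.60	119.12
V	4.2	-1.5	5.9	84	1.06	1.70	0.50	1.22	5.96	117.15
W	-0.9	-3.4	5.4	170	1.08	1.37	0.96	2.25	5.89	204.24
Y	-1.3	-2.3	6.2	136	0.69	1.47	1.14	0.96	5.66	181.19
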