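# SYNTHETIC stand-in for the 28-property AAindex subset used by the default
# physicochemical encoder.  Accession ids are the real selected set; the
# numeric values are NOT the AAindex1 release values (that database is not
# redistributed here).  Values follow each property's characteristic scale,
# sign structure and residue ordering so that feature code behaves
# realistically, but they must not be cited as AAindex data.  Replace this
# file with a conforming extract of AAindex1 for production use.
accession	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
CHOP780202	0.83	1.19	0.54	0.37	1.38	0.75	0.87	1.60	0.74	1.30	1.05	0.89	0.55	1.10	0.93	0.75	1.19	1.70	1.37	1.47
CIDH920103	0.04	0.86	-0.82	-0.77	1.69	-0.10	0.05	1.52	-1.13	1.46	1.18	-0.77	-0.21	-0.76	-0.87	-0.45	-0.18	1.26	1.39	1.21
CIDH920105	0.02	0.77	-0.71	-0.84	1.92	-0.24	-0.02	1.61	-1.24	1.53	1.05	-0.85	-0.36	-0.69	-0.94	-0.39	-0.12	1.33	1.48	1.05
FAUJ880109	0.0	0.0	1.0	1.0	0.0	0.0	1.0	0.0	2.0	0.0	0.0	2.0	0.0	2.0	4.0	1.0	1.0	0.0	1.0	1.0
FAUJ880111	0.0	0.0	0.0	0.0	0.0	0.0	0.5	0.0	1.0	0.0	0.0	0.0	0.0	0.0	1.0	0.0	0.0	0.0	0.0	0.0
FINA910104	1.08	0.92	1.05	1.21	0.89	1.26	1.02	0.84	1.14	0.92	0.97	1.17	1.32	1.04	1.09	1.13	1.03	0.83	0.87	0.94
GEIM800104	1.29	0.91	0.92	1.44	1.01	0.61	1.05	1.04	1.18	1.23	1.27	0.81	0.52	1.17	0.96	0.78	0.86	0.96	1.10	0.74
GEIM800106	0.86	1.25	0.79	0.69	1.25	0.89	0.88	1.42	0.80	1.13	1.09	0.80	0.68	0.96	0.92	1.03	1.14	1.52	1.22	1.32
KANM800102	0.95	1.07	0.86	0.78	1.34	0.88	0.96	1.45	0.81	1.21	1.11	0.84	0.64	0.95	0.90	0.99	1.14	1.49	1.23	1.28
KLEP840101	0.0	0.0	-1.0	-1.0	0.0	0.0	0.0	0.0	1.0	0.0	0.0	0.0	0.0	0.0	1.0	0.0	0.0	0.0	0.0	0.0
KRIW710101	5.1	4.2	6.6	6.1	3.1	6.0	5.2	2.8	7.9	3.0	3.4	6.7	5.9	6.2	7.5	6.1	5.4	2.9	3.2	4.1
LIFS790101	0.92	1.16	0.48	0.61	1.25	0.61	0.93	1.81	0.70	1.30	1.19	0.60	0.40	0.95	0.93	0.82	1.12	1.81	1.54	1.53
MEEJ800101	0.5	-6.8	-8.2	-16.9	13.2	0.0	-3.5	13.9	0.1	8.8	4.8	0.8	6.1	-4.8	0.8	1.2	2.7	2.7	14.9	6.1
OOBM770102	2.15	3.66	2.85	3.35	5.27	1.18	4.22	4.45	3.57	4.45	4.33	2.95	3.11	3.72	4.23	2.31	3.19	3.67	6.93	5.89
PALJ810107	0.89	1.18	0.71	0.53	1.30	0.91	0.91	1.54	0.77	1.26	1.09	0.75	0.59	0.98	0.90	0.92	1.17	1.64	1.28	1.45
QIAN880123	0.12	0.29	-0.41	-0.45	0.67	-0.14	0.04	0.81	-0.52	0.70	0.44	-0.38	-0.63	-0.22	-0.30	-0.19	0.09	0.79	0.51	0.55
RACS770103	1.9	1.1	3.1	3.4	0.6	2.3	1.6	0.5	4.6	0.5	0.7	3.0	2.6	3.2	4.5	2.4	1.9	0.6	1.0	1.4
RADA880108	-0.06	1.36	-0.80	-0.77	1.27	-0.41	0.49	1.31	-1.18	1.21	1.27	-0.48	0.0	-0.73	-0.84	-0.50	-0.27	1.09	0.88	0.33
ROSM880102	-0.67	0.38	-1.31	-1.22	2.46	0.0	0.64	2.97	-2.71	2.40	1.87	-0.92	-0.49	-0.91	-2.55	-0.55	-0.28	1.99	2.88	1.41
SWER830101	-0.40	0.17	-1.31	-1.22	1.92	-0.67	-0.64	1.25	-0.67	1.22	1.02	-0.92	-0.49	-0.91	-0.59	-0.55	-0.28	0.91	0.50	1.67
ZIMJ680102	11.50	13.46	11.68	13.57	19.80	3.40	13.69	21.40	15.71	21.40	16.25	12.82	17.43	14.45	14.28	9.47	15.77	21.57	21.67	18.03
ZIMJ680104	6.00	5.05	2.77	3.22	5.48	5.97	7.59	6.02	9.74	5.98	5.74	5.41	6.30	5.65	10.76	5.68	5.66	5.96	5.89	5.66
AURR980120	1.05	0.91	1.08	1.19	0.95	0.76	1.01	0.94	1.10	1.04	1.06	0.98	0.64	1.09	1.11	0.93	0.87	0.90	1.02	0.89
MUNV940101	0.98	1.04	1.11	1.06	0.93	1.16	1.02	0.88	1.05	0.92	0.95	1.10	1.24	1.03	1.01	1.08	1.04	0.87	0.96	0.99
NADH010104	2.01	3.35	-2.68	-2.45	4.37	0.16	-1.91	4.28	-3.76	3.93	3.04	-2.48	-0.98	-2.27	-3.42	-0.86	-0.22	3.67	2.29	1.05
NADH010106	1.92	3.56	-2.87	-2.60	4.51	0.27	-1.73	4.52	-4.02	4.11	3.26	-2.66	-1.12	-2.45	-3.71	-0.97	-0.31	3.89	2.51	1.23
GUYH850105	0.10	-1.42	0.78	0.83	-2.12	0.33	-0.50	-1.81	1.40	-1.80	-1.18	0.48	0.73	0.95	0.56	0.52	0.07	-1.56	-0.79	-0.88
MIYS990104	-0.04	-0.38	0.19	0.21	-0.55	0.09	-0.10	-0.61	0.26	-0.58	-0.42	0.14	0.15	0.13	0.07	0.10	0.01	-0.51	-0.48	-0.27
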