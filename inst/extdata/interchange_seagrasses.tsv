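source	NC	CI	CP	EA	EP	SC	WA	WI	NP
NC	0	0.5	0.14	1.38	0.08	0.12	0.81	0.71	0.13
CI	1.37	0	8.56	1.88	0.94	6.65	2.65	5.93	3.74
CP	0.14	1.54	0	0.25	0.22	0.82	0.96	1.14	0.21
EA	0.91	0.5	0.2	0	0.12	0.26	0.25	0.55	0.11
EP	0.08	0.51	0.42	0.24	0	0.2	0.49	0.28	0.61
SC	0.19	1.58	1.24	0.36	0.84	0	0.45	0.46	0.2
WA	0.2	1.6	1.75	1.21	1.37	0.25	0	1.64	0.2
WI	0.35	2.28	2.08	1.94	0.43	0.4	0.95	0	0.15
NP	1.13	2.66	0.25	1.09	1.73	0.48	0.49	0.51	0
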