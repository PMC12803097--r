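source	NC	CI	CP	EA	EP	SC	WA	WI	NP
NC	0	1.51	1.13	0.26	0.22	0.24	0.42	0.96	0.19
CI	0.49	0	22.38	1.64	6.65	1.89	2.66	33.28	1.85
CP	0.38	7.07	0	1.42	6.94	1.68	2.63	26.62	1.55
EA	0.12	1.64	1.62	0	0.29	0.27	0.82	1.22	0.22
EP	0.1	2.22	3.35	0.34	0	0.27	0.9	1.3	0.21
SC	0.18	2.43	1.88	0.42	0.35	0	0.47	1.39	0.31
WA	1.15	2.08	2.45	4.31	1.01	0.25	0	1.73	0.25
WI	0.34	6.52	13.74	1.02	4.26	0.87	1.9	0	1.33
NP	0.17	2.58	1.89	0.37	0.33	0.35	0.42	1.73	0
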