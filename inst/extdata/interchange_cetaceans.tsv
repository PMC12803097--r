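source	NC	CI	CP	EA	EP	SC	WA	WI	NP
NC	0	0.77	0.72	1.38	0.62	1.09	1.92	0.02	2.3
CI	0.66	0	0.88	2.39	1.78	1.6	2.14	0.58	1.08
CP	1.2	5.52	0	3.65	3.71	4.67	4.52	0.6	2.39
EA	2.38	2.78	1.03	0	1.19	2	4.6	0.53	0.8
EP	0.96	4.05	2.6	4.39	0	3.39	4.52	0.58	3.08
SC	0.71	2.14	3.92	1.32	3.81	0	2.56	0.07	1.24
WA	2.46	2.55	1.41	3.93	1.78	2.36	0	0.57	0.71
WI	0.2	1.05	0.12	0.1	0.04	0.1	0.14	0	0.02
NP	1.59	1.28	0.83	0.32	1.16	1.09	0.65	0.05	0
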