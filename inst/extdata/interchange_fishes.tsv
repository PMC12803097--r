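source	NC	CI	CP	EA	EP	SC	WA	WI	NP
NC	0	457.6	381.47	399.38	325.61	365.6	455.76	386.69	332.59
CI	585.82	0	807.38	543.94	521.04	560.8	680.89	861.31	466.3
CP	435.95	609.31	0	456.42	466.48	437.45	559.07	597.81	338.5
EA	392.11	450.19	362.52	0	345.82	297.5	449.42	379.71	255.35
EP	337.4	464.22	393.19	382.18	0	288.4	436.48	329.46	315.72
SC	374.92	463.23	392.53	362.82	304.76	0	400.39	343.8	262.44
WA	473.7	474.58	439.01	503.81	429.67	366.53	0	408.37	291.23
WI	370.32	533.07	435.47	426.45	346.1	328.19	449.97	0	276.3
NP	272.2	382.34	292.64	267.99	269.19	226.41	272.91	255.5	0
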