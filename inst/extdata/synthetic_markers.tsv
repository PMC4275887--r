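species	marker	mass	n_hydroxylations	diagnostic
sheep	COL1a1-S1	1180.62	0	TRUE
sheep	COL1a1-S2	1550.79	0	TRUE
sheep	COL1a2-S3	2131.06	0	TRUE
sheep	COL1a2-S4	2883.40	0	TRUE
sheep	COL1a2-S5	3093.48	0	TRUE
goat	COL1a1-G1	1180.62	0	TRUE
goat	COL1a1-G2	1566.78	0	TRUE
goat	COL1a2-G3	2163.09	0	TRUE
goat	COL1a2-G4	2883.40	0	TRUE
goat	COL1a2-G5	3077.45	0	TRUE
cow	COL1a1-C1	1192.61	0	TRUE
cow	COL1a1-C2	1566.78	0	TRUE
cow	COL1a2-C3	2131.06	0	TRUE
cow	COL1a2-C4	2853.38	0	TRUE
cow	COL1a2-C5	3033.44	0	TRUE
pig	COL1a1-P1	1192.61	0	TRUE
pig	COL1a1-P2	1582.80	0	TRUE
pig	COL1a2-P3	2115.05	0	TRUE
pig	COL1a2-P4	2869.41	0	TRUE
pig	COL1a2-P5	3017.42	0	TRUE
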