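mz	intensity
1105.57	220
1180.63	1900
1427.70	310
1550.80	1500
2131.05	1200
2200.33	150
2883.41	800
3093.47	950
3201.88	90
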