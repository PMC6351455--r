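participant	accuracy_pct	f1
01	49	0.44
02	54	0.44
03	34	0.40
04	41	0.42
05	61	0.57
06	51	0.50
07	44	0.42
08	41	0.18
09	52	0.44
10	46	0.31
11	42	0.35
12	43	0.55
13	55	0.52
14	42	0.38
15	48	0.37
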