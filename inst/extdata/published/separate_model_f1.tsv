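participant	back0	back1	back2	back3	back4
01	0.23	0.77	0.09	0.32	0.70
02	0.70	0.80	0.88	0.23	0.72
03	0.62	0.85	0.98	0.91	0.54
04	0.89	0.98	0.47	0.90	0.66
05	0.55	0.93	0.90	1.00	0.21
06	0.90	0.86	0.88	0.71	0.84
07	0.44	0.78	0.94	0.48	0.67
08	0.42	0.99	1.00	0.74	0.31
09	0.77	0.68	0.89	0.94	0.52
10	0.67	0.87	1.00	0.23	0.84
11	0.50	0.82	1.00	0.99	0.33
12	0.73	0.88	1.00	0.67	0.56
13	1.00	0.93	0.16	0.94	0.77
14	0.24	0.91	0.77	0.27	0.44
15	0.89	0.91	0.57	0.31	0.40
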