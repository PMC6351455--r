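pair_type	condition_a	condition_b	accuracy
within	0c	0nc	0.68
within	1c	1nc	0.87
within	2c	2nc	0.85
within	3c	3nc	0.72
within	4c	4nc	0.62
adjacent	0c	1nc	0.64
adjacent	1c	2nc	0.63
adjacent	2c	3nc	0.55
adjacent	3c	4nc	0.49
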