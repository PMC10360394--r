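group	outcome	a	b	c	d
significant	reported_dx	33	52	1154	5617
significant	high_traits	39	46	1840	4931
significant	dx_or_high	50	35	2282	4489
susceptibility	reported_dx	45	149	1154	5617
susceptibility	high_traits	69	125	1840	4931
susceptibility	dx_or_high	80	114	2282	4489
either	reported_dx	78	201	1154	5617
either	high_traits	108	171	1840	4931
either	dx_or_high	130	149	2282	4489
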