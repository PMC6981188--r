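position	ref_base	alt_base	weight
1	A	G	0.9
1	A	C	0.85
1	A	T	0.8
5	G	A	0.7
5	G	T	0.65
10	C	T	0.5
10	C	A	0.45
15	T	C	0.3
15	T	G	0.25
21	A	G	0.1
22	G	A	0
23	T	C	0
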