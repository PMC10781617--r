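variant	effect_allele	category	beta
pigvar01	T	blond	0.31
pigvar01	T	brown	0.784
pigvar01	T	red	3.242
pigvar02	A	blond	0.106
pigvar02	A	brown	1.441
pigvar02	A	red	-1.635
pigvar03	T	blond	-0.145
pigvar03	T	brown	1.254
pigvar03	T	red	0.165
pigvar04	A	blond	-1.433
pigvar04	A	brown	-1.204
pigvar04	A	red	-1.792
pigvar05	T	blond	0.734
pigvar05	T	brown	2.218
pigvar05	T	red	-1.765
pigvar06	G	blond	-0.261
pigvar06	G	brown	-0.8
pigvar06	G	red	0.15
pigvar07	C	blond	-0.219
pigvar07	C	brown	0.127
pigvar07	C	red	-1.196
pigvar08	C	blond	1.12
pigvar08	C	brown	-0.507
pigvar08	C	red	-0.002
pigvar09	G	blond	0.986
pigvar09	G	brown	-0.147
pigvar09	G	red	-0.514
pigvar10	A	blond	1.671
pigvar10	A	brown	0.226
pigvar10	A	red	-0.736
pigvar11	A	blond	-0.571
pigvar11	A	brown	0.143
pigvar11	A	red	-2.43
pigvar12	C	blond	0.78
pigvar12	C	brown	-0.03
pigvar12	C	red	-1.47
pigvar13	G	blond	1.669
pigvar13	G	brown	0.13
pigvar13	G	red	0.215
pigvar14	T	blond	-1.333
pigvar14	T	brown	-0.583
pigvar14	T	red	0.681
pigvar15	T	blond	-1.033
pigvar15	T	brown	-0.605
pigvar15	T	red	-0.591
pigvar16	C	blond	-1.358
pigvar16	C	brown	-1.993
pigvar16	C	red	0
pigvar17	T	blond	-1.751
pigvar17	T	brown	-0.459
pigvar17	T	red	1.347
pigvar18	A	blond	0.096
pigvar18	A	brown	-0.615
pigvar18	A	red	1.728
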