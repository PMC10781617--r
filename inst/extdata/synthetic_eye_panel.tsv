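variant	effect_allele	category	beta
pigvar01	A	blue	-2.929
pigvar01	A	intermediate	-0.941
pigvar02	A	blue	1.584
pigvar02	A	intermediate	-1.021
pigvar03	A	blue	-0.368
pigvar03	A	intermediate	-2.897
pigvar04	A	blue	-2.138
pigvar04	A	intermediate	0.043
pigvar05	C	blue	-0.206
pigvar05	C	intermediate	0.247
pigvar06	T	blue	1.458
pigvar06	T	intermediate	-0.433
pigvar07	C	blue	2.274
pigvar07	C	intermediate	0.91
pigvar08	C	blue	-0.517
pigvar08	C	intermediate	-0.872
pigvar09	A	blue	-0.309
pigvar09	A	intermediate	-1.642
pigvar10	T	blue	-2.116
pigvar10	T	intermediate	0.519
pigvar11	G	blue	0.552
pigvar11	G	intermediate	-0.974
pigvar12	T	blue	-0.768
pigvar12	T	intermediate	1.733
pigvar13	G	blue	0.547
pigvar13	G	intermediate	-0.518
pigvar14	T	blue	0.846
pigvar14	T	intermediate	0.787
pigvar15	A	blue	1.242
pigvar15	A	intermediate	0.386
pigvar16	A	blue	-0.731
pigvar16	A	intermediate	-0.941
pigvar17	C	blue	0.606
pigvar17	C	intermediate	1.891
pigvar18	T	blue	-2.06
pigvar18	T	intermediate	0.771
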