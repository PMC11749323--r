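chain1	chain2	mutated_chain	mutation	ddg	interface	deleterious
A	G	G	R419H	1.64	no	yes
A	G	G	K380R	0.44	yes	no
A	G	G	E451Q	0.03	no	no
A	G	G	G416S	1.35	no	no
A	G	G	E441K	1.23	no	no
A	G	G	F448S	0.29	no	no
A	G	G	A364T	0.41	no	no
A	G	G	A429V	-0.02	no	no
A	G	G	K380N	1.08	yes	no
A	G	G	K380R	0.44	yes	no
A	G	A	N92S	0.3	no	no
A	G	A	G245D	1.27	no	no
A	G	A	I267T	0.6	no	no
A	G	A	F21L	0.44	yes	no
A	G	A	L8M	0.19	no	no
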