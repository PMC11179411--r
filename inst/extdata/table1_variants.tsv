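individual	cdna	protein	group	v2_allele_count	v2_n_hemizygotes	v2_allele_freq	v2_hemizygote_freq	v4_allele_count	v4_n_hemizygotes	v4_allele_freq	v4_hemizygote_freq	metadome	revel	cadd	alphamissense	polyphen2
1	c.274C>T	p.Arg92Cys	1	0	0	0	0	11	3	9.09e-6	7.54e-6	1.31	0.404	24.7	NA	1.0
2	c.343G>A	p.Asp115Asn	1	1	0	5.58e-6	0	18	5	1.49e-5	1.26e-5	0.53	0.165	23.6	0.037	0.388
3	c.182_194del	p.Tyr61Cysfs*31	1	0	0	0	0	0	0	0	0	NA	NA	NA	NA	NA
4	c.295C>T	p.Arg99*	1	2	0	1.1e-5	0	6	2	4.96e-6	5.03e-6	NA	NA	35	NA	NA
5	c.1348A>T	p.Lys450*	1	1	0	5.51e-6	0	5	1	8.87e-6	4.99e-6	NA	NA	37	NA	NA
6	c.170C>T	p.Thr57Met	2	3	0	1.67e-5	0	12	0	9.92e-6	0	0.14	0.858	25.3	0.909	0.986
7	c.178C>T	p.Arg60Cys	2	0	0	0	0	2	0	1.82e-6	0	0.16	0.469	29.0	0.534	1.0
8	c.238G>C	p.Gly80Arg	2	0	0	0	0	0	0	0	0	0.36	0.101	18.14	0.145	0.001
9	c.320G>A	p.Arg107Gln	2	0	0	0	0	6	2	4.96e-6	5.03e-6	0.55	0.395	23.1	0.225	0.956
10	c.436C>T	p.Arg146Cys	2	1	0	5.71e-6	0	3	2	2.74e-6	8.78e-6	0.18	0.807	26.5	0.952	1.0
11	c.442G>A	p.Ala148Thr	2	0	0	0	0	1	0	2.2e-6	0	0.23	0.438	20.7	0.112	0.471
12	c.604G>A	p.Ala202Thr	2	5	2	2.53e-5	2.83e-5	130	35	1.08e-4	8.82e-5	0.74	0.613	22.7	0.207	0.236
13	c.922C>T	p.His308Tyr	2	0	0	0	0	0	0	0	0	0.69	0.774	25.3	0.970	0.786
14	c.1291C>T	p.Arg431Cys	2	2	1	1.11e-5	1.56e-5	5	3	4.58e-6	8.38e-6	1.79	0.694	33	0.936	1.0
15/16	c.1546A>T	p.Thr516Ser	2	11	3	5.81e-5	4.63e-5	277	79	2.3e-4	2.01e-4	0.9	0.157	15.87	0.102	0.044
17	c.1606A>G	p.Arg536Gly	2	3	2	1.68e-5	3.11e-5	32	14	2.65e-5	3.52e-5	0.46	0.822	25.1	0.194	0.949
18	c.1733A>T	p.Asn578Ile	2	0	0	0	0	0	0	0	0	0.55	0.814	26.9	0.756	1.0
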