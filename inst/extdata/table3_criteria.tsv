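individual	cdna	protein	criteria	classification
6	c.170C>T	p.Thr57Met	PS3,PM2_sup,PP3	likely pathogenic
7	c.178C>T	p.Arg60Cys	PM2_sup,PP3	VUS
8	c.238G>C	p.Gly80Arg	PS3,PM2_sup,BP4	VUS
9	c.320G>A	p.Arg107Gln	PS3	VUS
10	c.436C>T	p.Arg146Cys	PS3,PP3	VUS
11	c.442G>A	p.Ala148Thr	PS3,PM2_sup	VUS
12	c.604G>A	p.Ala202Thr	PS3,BS2	VUS
13	c.922C>T	p.His308Tyr	PS3,PM2_sup,PP3	likely pathogenic
14	c.1291C>T	p.Arg431Cys	PS3,PP3	VUS
15/16	c.1546A>T	p.Thr516Ser	PS3,BP4,BS2	VUS
17	c.1606A>G	p.Arg536Gly	PP3	VUS
18	c.1733A>T	p.Asn578Ile	PS3,PM2_sup,PP3	likely pathogenic
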