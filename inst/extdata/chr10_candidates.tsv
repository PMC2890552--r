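gene	id	posmed	fc_4m	fc_8m	de_listed	n_criteria
Heca	Mm.473073	No	NP	NP	No	0
AC153433.6	ENSAMUSG95817	No	NP	NP	No	0
Ccdc28a	Mm.296565	No	1	1.3	Yes	1
Nhsl1	Mm.297971	No	1	1	No	0
Hebp2	Mm.35551	Yes	NP	NP	No	1
Perp	Mm.28209	Yes	2.8	1	Yes	2
Tnfaip3	Mm.116683	Yes	1	1	No	1
D10Bwg1379e	Mm.425612	No	1	1	No	0
Olig3	Mm.156946	Yes	NP	NP	No	1
Il20ra	Mm.234667	No	NP	NP	No	0
Pex7	Mm.338363	Yes	0.8	1	Yes	2
Map3k5	Mm.6595	Yes	1	1	No	1
Mtap7	Mm.20928	Yes	1	1	No	1
Bclaf1	Mm.294783	No	1	1	No	0
Pde7b	Mm.425617	Yes	NP	NP	No	1
Ahi1	Mm.253280	Yes	NP	NP	No	1
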