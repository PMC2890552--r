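gene	id	posmed	fc_4m	fc_8m	de_listed	n_criteria
Fbln2	Mm.249146	Yes	1.8	1	No	2
Ctnna2	Mm.34637	Yes	NP	NP	No	1
Lrrtm4	Mm.94135	No	1	1	No	0
Tacr1	Mm.8055	Yes	NP	NP	No	1
Hk2	Mm.255848	Yes	1	1	No	1
Sema4f	Mm.270543	Yes	NP	NP	No	1
Dok1	Mm.156	Yes	1	1	No	1
Htra2	Mm.21880	Yes	1	1	No	1
Vax2	Mm.307165	Yes	NP	NP	No	1
Cyp26b1	Mm.255246	Yes	NP	NP	No	1
Rab11fip5	Mm.220334	No	1	1	No	0
Alms1	Mm.246967	Yes	1	1	No	1
Tgfa	Mm.137222	Yes	1.4	1.8	Yes	2
Gmcl1	Mm.321452	No	1	1.3	Yes	1
Anxa4	Mm.259702	No	1	1	No	0
Aak1	Mm.221038	Yes	1	1	No	1
Nfu1	Mm.23809	No	1	0.8	Yes	1
Gfpt1	Mm.19893	Yes	0.5	0.5	Yes	2
Antxr1	Mm.232525	Yes	1.4	1	Yes	2
Gkn1	Mm.46414	No	1	0.9	Yes	1
Arhgap25	Mm.119564	No	NP	NP	No	0
Ccdc48	Mm.333229	No	NP	NP	No	0
Cnbp	Mm.290251	No	1	1	No	0
Isy1	Mm.241546	No	NP	NP	No	0
Gata2	Mm.476843	Yes	1	1	No	1
Eefsec	Mm.333237	Yes	1	1	No	1
Wnt7a	Mm.56964	Yes	NP	NP	No	1
Slc6a6	Mm.395650	Yes	0.8	1	No	2
Grip2	Mm.333264	No	NP	NP	No	0
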