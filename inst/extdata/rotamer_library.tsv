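res_type	name	prob	chi1	chi2	chi3	chi4
SER	p	0.48	62	NA	NA	NA
SER	m	0.29	-65	NA	NA	NA
SER	t	0.22	180	NA	NA	NA
CYS	m	0.5	-65	NA	NA	NA
CYS	t	0.26	-177	NA	NA	NA
CYS	p	0.23	62	NA	NA	NA
THR	p	0.49	62	NA	NA	NA
THR	m	0.43	-65	NA	NA	NA
THR	t	0.07	-175	NA	NA	NA
VAL	t	0.73	175	NA	NA	NA
VAL	m	0.2	-60	NA	NA	NA
VAL	p	0.06	63	NA	NA	NA
LEU	mt	0.59	-65	175	NA	NA
LEU	tp	0.29	-177	65	NA	NA
LEU	mp	0.02	-85	65	NA	NA
LEU	tt	0.02	-172	147	NA	NA
ILE	mt	0.6	-65	170	NA	NA
ILE	mm	0.15	-57	-60	NA	NA
ILE	pt	0.13	62	170	NA	NA
ILE	tt	0.08	-177	166	NA	NA
MET	mtp	0.2	-65	180	75	NA
MET	mtt	0.15	-65	180	180	NA
MET	mmm	0.15	-65	-65	-70	NA
MET	ttp	0.1	-177	180	75	NA
ASP	m-20	0.51	-70	-15	NA	NA
ASP	t30	0.24	-177	30	NA	NA
ASP	p-10	0.14	62	-10	NA	NA
ASN	m-40	0.33	-65	-40	NA	NA
ASN	t-20	0.25	-174	-20	NA	NA
ASN	p-10	0.12	62	-10	NA	NA
ASN	m120	0.1	-65	120	NA	NA
GLU	mt-10	0.36	-67	177	-10	NA
GLU	tt0	0.24	-177	177	0	NA
GLU	mm-40	0.13	-65	-75	-40	NA
GLU	pt-20	0.08	62	180	-20	NA
GLN	mt-30	0.38	-67	180	-25	NA
GLN	tt0	0.16	-177	177	0	NA
GLN	mm-40	0.14	-65	-65	-40	NA
GLN	pt20	0.07	62	180	20	NA
LYS	tttt	0.27	-177	180	180	180
LYS	mttt	0.25	-65	180	180	180
LYS	mmtt	0.06	-65	-68	180	180
LYS	ttmt	0.05	-177	180	-65	180
ARG	mtt180	0.13	-67	180	180	180
ARG	mtm180	0.11	-67	180	-65	180
ARG	ttt180	0.09	-177	177	180	180
ARG	mtp180	0.08	-67	180	65	180
HIS	m-70	0.29	-65	-70	NA	NA
HIS	t75	0.2	-177	75	NA	NA
HIS	p-75	0.14	62	-75	NA	NA
PHE	m-85	0.44	-65	-85	NA	NA
PHE	t80	0.33	-177	80	NA	NA
PHE	p90	0.13	62	90	NA	NA
TYR	m-85	0.43	-65	-85	NA	NA
TYR	t80	0.34	-177	80	NA	NA
TYR	p90	0.13	62	90	NA	NA
TRP	m95	0.32	-65	95	NA	NA
TRP	t-105	0.19	-177	-105	NA	NA
TRP	p-90	0.11	62	-90	NA	NA
PRO	exo	0.44	29	-37	NA	NA
PRO	endo	0.44	-27	36	NA	NA
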