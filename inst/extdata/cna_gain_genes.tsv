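gene	stage	eoc_datasets	cytoband	gorringe_pct	known_cna	tcga_pct
CCT3	PE	2	1q23	36	-	44
CDC42SE1	PE	1	1q21.1	37	-	47
S100A6	PE	1	1q21	36	-	45
DNAJB11	PE	2	3q27	51	-	64
PAK2	PE	2	3q29	47	true	58
SERP1	PE	2	3q25.1	43	-	56
IGF2BP2	PE/EM	1	3q27.2	52	-	66
ISY1	PE	1	3q21.3	31	-	41
RPN1	PE	1	3q21.3	32	true	41
SQLE	PE	3	8q24.1	57	-	65
PTK2	PE	3	8q24.3	55	true	61
TPD52	PE	3	8q21	32	-	39
DERL1	PE	2	8q24.13	54	-	63
KRAS	PE	2	12p12.1	32	-	40
FKBP4	PE	2	12p13.33	39	-	36
NCAPD2	EM	2	12p13.31	37	-	35
BCAT1	PE/EM	1	12pter-q12	32	-	39
MGST1	PE	1	12p12.3-p12.1	30	-	36
UBE2C	PE	3	20q13.12	37	-	39
EYA2	PE	2	20q13.1	41	true	41
AHCY	PE	2	20q11.22	33	-	37
KIF3B	PE	1	20q11.21	35	true	40
CTSA	EM	1	20q13.12	37	-	38
TTPAL	PE	1	20q13.12	34	-	38
EPB41L1	PE	1	20q11.2-q12	31	-	36
CLPTM1L	PE	2	5p15.33	31	-	36
BRD4	EM	1	19	29	true	37
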