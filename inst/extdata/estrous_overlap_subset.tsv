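gene	stage	eoc_datasets	direction	pubmed_hits
EPCAM	PE	4	up	43
KIAA0101	PE/EM	4	up	0
NME1	PE	3	up	53
SPINT2	PE	3	up	24
PTK2	PE	3	up	24
EZR	PE	3	down	13
GATA6	PE	3	down	12
CLDN3	PE	3	up	7
UBE2C	PE	3	up	4
SLC34A2	PE	3	up	3
TPD52	PE	3	up	3
DHCR24	PE	3	up	1
PTPRF	PE/EM	3	up	1
ARF1	PE	3	up	1
CYCS	PE	3	up	0
HSPE1	PE	3	up	0
F11R	PE	3	up	0
HMGB3	PE/EM	3	up	0
ATP11A	PE	3	down	0
NUAK2	PE	3	up	0
CACYBP	PE	3	up	0
PAK1IP1	PE/EM	3	up	0
NAA50	PE	3	up	0
SQLE	PE	3	up	0
CTSC	PE	3	up	0
C5orf34	EM	3	up	0
MUM1L1	PE	3	down	0
EZH2	PE	2	up	4
LCN2	PE	2	up	13
SMARCA4	PE	2	up	6
BIRC5	PE/EM	1	up	109
MAPK1	PE	1	up	78
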