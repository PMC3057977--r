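gene	stage	eoc_datasets	direction	ref	ovarian	other	fusion
PTK2	PE	3	up	-	0/26	1/476 CNS, 1/6 skin, 2/226 lung
NUAK2	PE	3	up	greenman	1/26	1/82 breast
KRAS	PE	2	up	futreal	377/2754	mutations in multiple organs
NRAS	PE	2	up	futreal	3/108	mutations in multiple organs
SMARCA4	PE	2	up	futreal	1/28	mutations in multiple organs
CDH1	EM	1	up	futreal	1/84	mutations in multiple organs
BRD4	EM	1	up	futreal	0/26	0/264
KIAA0101	PE/EM	4	up	-	-	1/22 CNS
MDM4	PE	3	inconsistent	futreal	-	1/447 CNS, 1/3 aerodigestive tract
SFPQ	PE/EM	3	inconsistent	futreal	-	1/6 skin	TFE3; kidney and soft tissue
MALAT1	EM	3	down	futreal	no record
C5orf34	EM	3	up	-	-	1/48 breast
CYCS	PE	3	up	-	-	1/11 lung
MUM1L1	PE	3	down	-	-	1/6 skin
GATA6	PE	3	down	-	-	3/446 CNS
TPM4	PE	2	up	futreal	-	1/48 breast	ALK; haematopoietic and soft tissue
EZH2	PE	2	up	futreal	-	58/690 haematopoietic tissue, 1/38 intestine, 1/6 skin
JUN	PE	2	up	futreal	-	0/783
FOXO1	PE	2	down	futreal	-	1/447 CNS
DICER1	PE/EM	1	up	futreal	-	1/11 lung, 1/6 skin
SUZ12	EM	1	up	futreal	-	0/171	JAZF1; endometrial and soft tissue
HSP90AB1	PE	1	up	futreal	-	0/171
MSN	PE	1	down	futreal	-	0/595	ALK; haematopoietic tissue
RPN1	PE	1	up	futreal	no record
HNRNPA2B1	PE	1	down	futreal	no record
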