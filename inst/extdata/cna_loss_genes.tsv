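gene	stage	eoc_datasets	cytoband	gorringe_pct	known_cna	tcga_pct
FAT4	EM	2	4q28.1	35	-	51
PHF17	PE	2	4q26-q27	34	-	51
MAPKSP1	PE	1	4q24-q26	34	-	55
ST13	PE	1	22q13.2	35	-	70
TEF	PE/EM	1	22q13.2	34	true	70
HMOX1	PE	1	22q12	31	-	63
TIMP3	PE	1	22q12.3	34	-	61
EZR	PE	3	6q25.3	33	-	51
CIRBP	PE/EM	2	19p13.3	34	true	77
EFNB3	EM	1	17p13.1	30	-	66
IGFBP4	PE/EM	1	17q12-q21.1	30	-	67
TK2	EM	1	16q22-q23.1	35	-	64
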