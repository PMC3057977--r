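gene	tothill	bonome	donninger	lu	heinzelmann
CD24	68.6	47.7	56.2	>3	up
MAL2	3.4	3.0	3.1	>3	up
ESRP1	8.2	8.1	4.5	-	up
EPCAM	7.6	10.4	38.9	-	up
LRIG1	7.1	5.9	4.5	>3	-
SPP1	7.0	2.6	-	>3	up
WFDC2	6.2	17.7	-	>3	up
MTHFD2	6.1	6.9	-	>3	up
MUC1	5.1	6.1	4.1	>3	-
CP	4.7	50.6	18.7	>3	-
PRKCI	4.3	2.7	2.2	>3	-
KPNA2	4.1	2.4	-	>3	up
VEGFA	3.6	2.1	1.6	>3	-
ERBB3	3.3	2.6	-	>3	up
KIAA0101	2.6	7.3	-	>3	up
SMC4	2.3	3.5	2.7	>3	-
ANXA8	-23.6	-25.6	-34.4	na	na
CALB2	-21.8	-47.6	-57.8	na	na
FAM153C	-19.3	-25.0	-27.5	na	na
REEP1	-15.7	-25.6	-9.8	na	na
C13orf36	-15.4	-20.0	-14.6	na	na
PCOLCE2	-11.0	-8.6	-2.7	na	na
LRRN4	-10.0	-6.3	-8.2	na	na
EFEMP1	-9.2	-16.5	-8.4	na	na
MUM1L1	-8.6	-21.7	-5.9	na	na
TCEAL2	-8.5	-29.4	-12.8	na	na
MNDA	-7.6	-24.4	-8.8	na	na
C8orf84	-7.5	-7.7	-8.8	na	na
DPYD	-6.7	-15.9	-4.5	na	na
FLRT2	-5.5	-30.3	-15.3	na	na
PDGFD	-4.8	-14.9	-4.4	na	na
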