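patient_id	study	clinical_dx	locus_id	gene	motif	allele1_units	allele2_units	benign_motif	benign1_units	benign2_units	methylated	rank	result
P1	validation	HD	HTT	HTT	CAG	18	42				FALSE	1	HD
P2	validation	SCA3	ATXN3	ATXN3	CAG	11	72				FALSE	1	SCA3
P3	validation	SCA6	CACNA1A	CACNA1A	CAG	13	22				FALSE	2	SCA6
P4	validation	MyD	DMPK	DMPK	CTG	29	95				FALSE	2	MyD
P5	validation	SCA8	ATXN8OS	ATXN8OS/ATXN8	CTG	86	168	CTA	9	11	FALSE	1	SCA8
P6	validation	NIID	NOTCH2NLC	NOTCH2NLC	GGC	19	185				FALSE	1	NIID
P7	validation	CCHS	PHOX2B	PHOX2B	GCC	19	26				FALSE	1	CCHS
P8	validation	BAFME	SAMD12	SAMD12	TTTCA	0	167	TTTTA	17	500	FALSE	1	BAFME
P9	validation	CANVAS	RFC1	RFC1	AAGGG	622	622				FALSE	1	CANVAS
P10	validation	SCA31	BEAN1	BEAN1	TGGAA	0	373				FALSE	1	SCA31
P11	validation	SCA36	NOP56	NOP56	GGCCTG	10	1593				FALSE	1	SCA36
P12	validation	ULD	CSTB	CSTB	CCCCGCCCCGCG	40	70				FALSE	1	ULD
I1	methylation	Asymptomatic carrier	NOTCH2NLC	NOTCH2NLC	GGC	26	510				TRUE	1	Carrier
P13	discovery	SCA	CACNA1A	CACNA1A	CAG	16	21				FALSE	1	SCA6
P14	discovery	SCA	BEAN1	BEAN1	TGGAA	0	249				FALSE	1	SCA31
P15	discovery	SCA	CACNA1A	CACNA1A	CAG	20	21				FALSE	1	SCA6
P16	discovery	SCA	BEAN1	BEAN1	TGGAA	0	269				FALSE	1	SCA31
P17	discovery	SCA	ATXN8OS	ATXN8OS/ATXN8	CTG	12	47	CTA	8	19	FALSE	1	Intermediate expansion in SCA8 locus
P18	discovery	CANVAS	RFC1	RFC1	AAGGG	714	988				FALSE	1	CANVAS
P19	discovery	CANVAS	RFC1	RFC1	AAGGG	682	927				FALSE	1	CANVAS
P20	discovery	SCA									FALSE		No known repeat expansion
P21	discovery	SCA									FALSE		No known repeat expansion
P22	discovery	SCA									FALSE		No known repeat expansion
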