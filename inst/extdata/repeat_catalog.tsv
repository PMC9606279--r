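locus_id	gene	disease	chrom	start	end	pathogenic_motifs	benign_motifs	interruption_motifs	ref_units	normal_max_units	pathogenic_min_units	inheritance	motif_len
HTT	HTT	Huntington disease	chr4	3074877	3074940	CAG		CAACAG,CCG	21	26	36	AD	3
ATXN3	ATXN3	SCA3	chr14	92071011	92071041	CAG		CGG	10	44	60	AD	3
CACNA1A	CACNA1A	SCA6	chr19	13207859	13207898	CAG			13	18	20	AD	3
DMPK	DMPK	Myotonic dystrophy type 1	chr19	45770205	45770265	CTG		CCG,CGG,CAG,CTC	20	34	50	AD	3
ATXN8OS	ATXN8OS/ATXN8	SCA8	chr13	70139384	70139429	CTG	CTA	CCG	15	40	71	AD	3
NOTCH2NLC	NOTCH2NLC	NIID	chr1	149390803	149390842	GGC		GGA	13	40	60	AD	3
PHOX2B	PHOX2B	CCHS	chr4	41745972	41746032	GCC,GCG,GCA,GCT			20	20	25	AD	3
SAMD12	SAMD12	BAFME1	chr8	118366813	118366913	TTTCA	TTTTA		20	20	100	AD	5
RFC1	RFC1	CANVAS	chr4	39348425	39348480	AAGGG,ACAGG	AAAAG,AAAGG		11	100	400	AR	5
BEAN1	BEAN1	SCA31	chr16	66490397	66490462	TGGAA	TAAAA,TAGAA		13	0	45	AD	5
TNRC6A	TNRC6A	Polymorphic pentanucleotide repeat	chr16	24613439	24613489	TTTCA	TTTTA		10			unknown	5
NOP56	NOP56	SCA36	chr20	2652733	2652757	GGCCTG		GGA	4	14	650	AD	6
CSTB	CSTB	Progressive myoclonic epilepsy 1	chr21	43776443	43776479	CCCCGCCCCGCG			3	3	30	AR	12
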