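line	chrom	pos_1based	ref_alt	zygosity	gene_note
2B-52	ChrIII	145135	A>G	heterozygous	CWH43 L832L
2B-52	ChrIV	1062644	G>A	heterozygous	PRO1 H49Y
2B-52	ChrVIII	150074	G>C	heterozygous	YHR022C F89V
2B-52	ChrX	631351	G>T	heterozygous	CPA2 N527K
2B-52	ChrX	673974	C>T	heterozygous	SGM1 L623L
3B-87	ChrI	177541	G>T	heterozygous
3B-87	ChrIII	117835	A>C	heterozygous	CDC10 I171R
3B-87	ChrIV	962798	G>T	heterozygous	PAM1 A730S
3B-87	ChrIV	1026680	C>A	heterozygous	GCN2 D1123Y
3B-87	ChrV	563878	T>A	heterozygous
3B-87	ChrXIII	209683	G>A	heterozygous	SRC1 Q53Q
3B-87	ChrXVI	545073	C>A	heterozygous	NCR1 A149E
3B-87	ChrXVI	656427	G>A	heterozygous	YPR045C L42L
4B-87	ChrIV	66310	A>G	heterozygous
4B-87	ChrIV	66758	G>A	heterozygous	YDL218W A89T
4B-87	ChrX	193151	A>G	heterozygous	PHO86 N208S
4B-87	ChrX	471267	C>A	heterozygous	BNA1 V133F
4B-87	ChrXII	706989	T>G	heterozygous	ECI1 P18P
4B-87	ChrXIII	670507	G>T	heterozygous	INP1 S273Y
3T-50	ChrIV	180916	A>G	homozygous	MSH5 K861R
3T-50	ChrIV	601543	G>T	homozygous	SED1 L91F
3T-50	ChrIX	290215	A>G	homozygous
3T-50	ChrX	677807	G>A	homozygous	TTI2 T107I
3T-50	ChrXVI	187332	A>T	homozygous	NAB3 E131D
4T-50	ChrIII	156792	G>T	homozygous	HSP30 S104S
4T-50	ChrXII	793815	C>T	homozygous
4T-50	ChrXIII	534158	C>A	homozygous	RRB1 L180F
4T-50	ChrXV	45147	G>T	homozygous	DCP1 D71Y
4T-50	ChrXV	226642	C>A	homozygous
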