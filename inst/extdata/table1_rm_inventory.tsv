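strain	locus_tag	location	annotation	length_nt	class	motif	meth_pos
TMW 2.1023	JGY91_01640	chromosome	Type I restriction modification subunit M	198_trunc.	I	None
TMW 2.1023	JGY91_13160	plasmid	Type I restriction endonuclease subunit S	1170	I	TCANNNNNNCTC/GAGNNNNNNTGA	3/2
TMW 2.1023	JGY91_13165	plasmid	Type I restriction modification system subunit M	1557	I
TMW 2.1023	JGY91_13170	plasmid	Type I restriction endonuclease subunit S	576	I
TMW 2.1023	JGY91_13175	plasmid	Type I restriction endonuclease subunit R	2787	I
TMW 2.1023	JGY91_01725	chromosome	DUF3578 domain-containing protein_McrBP	2028	IV
TMW 2.1023	JGY91_01730	chromosome	Hypothetical protein_McrCP	1323	IV
TMW 2.1324	JGY90_00145	chromosome	AlwI family type II restriction endonuclease	2121	II	GCATC/GATGC	3/2
TMW 2.1324	JGY90_00150	chromosome	DNA-(adenine-N6)-methyltransferase	2127	II
TMW 2.1324	JGY90_14115	plasmid	Type I restriction endonuclease subunit S	1185	I	ACCNNNNNRTGT/ACAYNNNNNGGT	1/3
TMW 2.1324	JGY90_14120	plasmid	Type I restriction modification subunit M	1557	I
TMW 2.1324	JGY90_14125	plasmid	Type I restriction endonuclease subunit S	576	I
TMW 2.1324	JGY90_14130	plasmid	Type I restriction endonuclease subunit R	2787	I
TMW 2.1521	JGY89_12325	chromosome	DEAD/DEAH box helicase	4737	IIG	GGGTNA	6
TMW 2.1521	JGY89_12080	chromosome	Type I restriction modification subunit M	198_trunc.	I
TMW 2.1521	JGY89_11995	chromosome	DUF3578 domain-containing protein_McrBP	2028	IV
TMW 2.1521	JGY89_11990	chromosome	Hypothetical protein_McrCP	1323	IV
TMW 2.1523	JGY88_00145	chromosome	DEAD/DEAH box helicase	4728	IIG	GGGTNA	6
TMW 2.1602				 	none	CACCG	4
TMW 2.1693	LHJ66_02060	chromosome	Type I restriction modification subunit M	1515	I	GACNNNNNTGT/ACANNNNNGTC	2/3
TMW 2.1693	LHJ66_02065	chromosome	Type I restriction endonuclease subunit S	1215	I
TMW 2.1693	LHJ66_02070	chromosome	Type I restriction endonuclease subunit R	3123	I
TMW 2.1693	LHJ66_02820	chromosome	DNA cytosine methyltransferase	1287	II
TMW 2.1693	LHJ66_13490	plasmid?	Site-specific DNA methyltransferase	2001	III	GCTCA	5
TMW 2.1693	LHJ66_13495	plasmid?	DEAD/DEAH box helicase family protein	2700	III
TMW 2.1704	LHJ68_05155	chromosome	DNA cytosine methyltransferase	1047	II
TMW 2.1704	LHJ68_05160	chromosome	DNA cytosine methyltransferase	1080	II
TMW 2.1704	LHJ68_05170	chromosome	DNA cytosine methyltransferase	1188	II
TMW 2.1780	LHJ67_11845	chromosome	DEAD_DEAH box helicase family protein	4737	IIG	GGGTNA	6
2	DWB98_00235	chromosome	Type I restriction modification subunit M	1464	I
2	DWB98_00240	chromosome	Type I restriction endonuclease subunit S	1164	I
2	DWB98_00245	chromosome	Type I restriction endonuclease subunit R	3354	I
DMSX03	DMSX03_RS00135	chromosome	Site-specific DNA-methyltransferase	1923	III
DMSX03	DMSX03_RS00140	chromosome	Restriction endonuclease	2967	III
DMSX03	DMSX03_RS00200	chromosome	DUF3578 domain-containing protein_McrBP	2034	IV
DMSX03	DMSX03_RS00205	chromosome	Hypothetical protein_McrCP	1323	IV
HKUOPL8	BE24_RS11845	chromosome	Type I restriction modification subunit M	1515	I
HKUOPL8	BE24_RS11850	chromosome	Type I restriction endonuclease subunit S	1251	I
HKUOPL8	BE24_RS11855	chromosome	Type I restriction endonuclease subunit R	3123	I
HKUOPL8	BE24_RS11615	chromosome	Cytosine methyltransferase	1080	II	CCCGT
HKUOPL8	BE24_RS11620	chromosome	DNA methyltransferase	1047	II	CCCGT
HKUOPL8	BE24_RS13495	chromosome	AAA family ATPase	1473	II
HKUOPL8	BE24_RS11635	chromosome	LlaJI family restriction endonuclease	1122	II
HKUOPL8	BE24_RS05200	chromosome	DNA methyltransferase (C5)	957	II
S170	AWC37_RS12155	chromosome	Type I restriction modification subunit M	1515	I
S170	AWC37_RS12160	chromosome	Type I restriction endonuclease subunit S	1263	I
S170	AWC37_RS12165	chromosome	Type I restriction endonuclease subunit R	3123	I
S170	AWC37_RS12130	chromosome	DUF3578 domain-containing protein_McrBP	2034	IV
S170	AWC37_RS12125	chromosome	Hypothetical protein_McrCP	1323	IV
SMQ-121	SXYLSMQ121_RS00165	chromosome	Type I restriction modification subunit M	1515	I	CACNNNNRTTG/GTGNNNNYAAC	2/9
SMQ-121	SXYLSMQ121_RS00160	chromosome	Type I restriction endonuclease subunit S	1266	I
SMQ-121	SXYLSMQ121_RS00155	chromosome	Type I restriction endonuclease subunit R	3123	I
SMQ-121	SXYLSMQ121_RS00195	chromosome	DUF3578 domain-containing protein_McrBP	2034	IV
SMQ-121	SXYLSMQ121_RS00195	chromosome	Hypothetical protein_McrCP	1317	IV
C2a	SXYL_RS00155	chromosome	Restriction endonuclease subunit R	423	I
C2a	SXYL_RS00165	chromosome	DUF3578 domain-containing protein_McrBP	2034	IV
C2a	SXYL_RS00170	chromosome	Hypothetical protein_McrCP	1317	IV
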