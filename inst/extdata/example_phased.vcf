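##fileformat=VCFv4.2
##source=sweepscan
##contig=<ID=1,length=196638>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	Yanbian_1	Yanbian_2	Yanbian_3	Yanbian_4	Hanwoo_1	Hanwoo_2	Hanwoo_3	Hanwoo_4
1	6794	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	0|1	1|0	1|1
1	9811	.	A	C	.	PASS	.	GT	1|1	1|1	1|0	1|1	0|1	0|1	0|1	1|1
1	10388	.	A	C	.	PASS	.	GT	0|0	0|0	1|1	1|0	0|0	0|0	0|1	0|0
1	11110	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|0	0|0	1|0	0|0
1	13608	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|0	1|1	1|1
1	15053	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|0	1|0	1|1	0|0
1	19160	.	A	C	.	PASS	.	GT	0|0	0|0	1|1	1|0	1|1	1|1	1|1	1|1
1	20083	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|1	0|0	0|0	1|1
1	20415	.	A	C	.	PASS	.	GT	1|0	1|1	0|0	1|1	0|0	0|0	0|0	0|0
1	23987	.	A	C	.	PASS	.	GT	0|1	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	24584	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	25004	.	A	C	.	PASS	.	GT	0|0	0|0	1|0	1|0	0|0	1|0	0|0	1|1
1	26791	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	28566	.	A	C	.	PASS	.	GT	1|0	1|1	0|0	0|1	0|0	1|1	1|0	1|1
1	31858	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	1|1	1|0	1|0	1|1
1	35234	.	A	C	.	PASS	.	GT	1|0	1|1	0|0	0|1	1|1	1|1	1|1	1|1
1	39554	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	1|1	1|1	1|1
1	42967	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	0|0	1|1
1	44001	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
1	50273	.	A	C	.	PASS	.	GT	0|0	1|1	1|1	1|1	1|1	1|1	1|0	1|1
1	54797	.	A	C	.	PASS	.	GT	0|0	1|1	0|0	0|0	0|0	1|0	1|0	1|1
1	57006	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	60138	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	1|0	0|0	0|0
1	63878	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	65232	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|0
1	67554	.	A	C	.	PASS	.	GT	0|1	1|1	1|1	1|1	0|0	0|0	1|0	0|0
1	80351	.	A	C	.	PASS	.	GT	0|1	1|1	0|0	0|0	1|1	1|1	1|1	1|1
1	82974	.	A	C	.	PASS	.	GT	0|0	1|1	1|1	1|1	0|0	1|1	1|1	1|0
1	83170	.	A	C	.	PASS	.	GT	0|0	0|0	1|1	1|1	1|1	1|1	0|0	1|1
1	83873	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	85354	.	A	C	.	PASS	.	GT	1|0	1|1	1|1	1|1	0|0	1|1	1|1	1|1
1	88514	.	A	C	.	PASS	.	GT	1|0	0|1	0|1	0|0	0|1	0|0	0|0	0|0
1	91547	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	97709	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	1|1	1|1	1|0	1|0
1	102582	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
1	104774	.	A	C	.	PASS	.	GT	1|0	0|1	0|0	0|0	1|0	1|1	1|0	1|0
1	116289	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|0	1|1	1|1	1|1
1	123612	.	A	C	.	PASS	.	GT	0|0	0|1	0|0	0|0	0|1	1|1	1|0	0|0
1	124750	.	A	C	.	PASS	.	GT	1|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	125124	.	A	C	.	PASS	.	GT	1|0	1|1	1|1	1|1	1|1	1|1	1|1	1|0
1	127102	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
1	132308	.	A	C	.	PASS	.	GT	0|0	0|0	0|0	1|0	1|0	0|0	0|1	1|1
1	140299	.	A	C	.	PASS	.	GT	0|0	1|0	1|0	0|1	0|1	1|0	0|0	0|1
1	142891	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|0	0|1	1|1
1	142978	.	A	C	.	PASS	.	GT	0|0	0|1	0|0	0|0	0|1	0|0	0|0	0|0
1	143315	.	A	C	.	PASS	.	GT	1|0	1|1	1|0	1|1	0|1	1|1	1|0	0|1
1	145351	.	A	C	.	PASS	.	GT	1|1	0|0	0|1	1|0	0|0	1|1	1|0	0|1
1	145513	.	A	C	.	PASS	.	GT	0|0	0|1	0|0	1|0	0|1	0|0	0|0	0|0
1	146961	.	A	C	.	PASS	.	GT	1|1	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	147348	.	A	C	.	PASS	.	GT	1|1	1|0	1|1	0|1	0|1	1|1	1|1	1|1
1	151239	.	A	C	.	PASS	.	GT	0|0	1|1	1|0	1|1	0|0	0|0	0|0	0|0
1	151882	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	0|0	0|1	1|0
1	152554	.	A	C	.	PASS	.	GT	0|0	0|0	0|1	0|0	0|1	0|0	0|0	0|0
1	155161	.	A	C	.	PASS	.	GT	0|0	1|0	1|0	0|1	0|1	1|0	0|0	1|1
1	158194	.	A	C	.	PASS	.	GT	1|0	1|1	0|1	1|1	1|0	0|1	1|1	1|1
1	167966	.	A	C	.	PASS	.	GT	0|0	1|0	1|0	0|1	0|0	1|0	0|1	1|0
1	183740	.	A	C	.	PASS	.	GT	1|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	186414	.	A	C	.	PASS	.	GT	1|0	1|1	1|1	1|1	1|0	1|1	1|1	1|1
1	187227	.	A	C	.	PASS	.	GT	1|1	1|1	1|0	1|1	1|1	0|1	1|1	0|1
1	196638	.	A	C	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
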