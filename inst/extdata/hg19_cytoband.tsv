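chr1	0	121500000	p11	gneg
chr1	121500000	1.25e+08	p11.1	acen
chr1	1.25e+08	128900000	q11.1	acen
chr1	128900000	249250621	q11	gneg
chr2	0	90500000	p11	gneg
chr2	90500000	93300000	p11.1	acen
chr2	93300000	96800000	q11.1	acen
chr2	96800000	243199373	q11	gneg
chr3	0	87900000	p11	gneg
chr3	87900000	9.1e+07	p11.1	acen
chr3	9.1e+07	93900000	q11.1	acen
chr3	93900000	198022430	q11	gneg
chr4	0	48200000	p11	gneg
chr4	48200000	50400000	p11.1	acen
chr4	50400000	52700000	q11.1	acen
chr4	52700000	191154276	q11	gneg
chr5	0	46100000	p11	gneg
chr5	46100000	48800000	p11.1	acen
chr5	48800000	50700000	q11.1	acen
chr5	50700000	180915260	q11	gneg
chr6	0	58700000	p11	gneg
chr6	58700000	6.1e+07	p11.1	acen
chr6	6.1e+07	63300000	q11.1	acen
chr6	63300000	171115067	q11	gneg
chr7	0	5.8e+07	p11	gneg
chr7	5.8e+07	59900000	p11.1	acen
chr7	59900000	61700000	q11.1	acen
chr7	61700000	159138663	q11	gneg
chr8	0	43100000	p11	gneg
chr8	43100000	45600000	p11.1	acen
chr8	45600000	48100000	q11.1	acen
chr8	48100000	146364022	q11	gneg
chr9	0	47300000	p11	gneg
chr9	47300000	4.9e+07	p11.1	acen
chr9	4.9e+07	50700000	q11.1	acen
chr9	50700000	141213431	q11	gneg
chr10	0	3.8e+07	p11	gneg
chr10	3.8e+07	40200000	p11.1	acen
chr10	40200000	42300000	q11.1	acen
chr10	42300000	135534747	q11	gneg
chr11	0	51600000	p11	gneg
chr11	51600000	53700000	p11.1	acen
chr11	53700000	55700000	q11.1	acen
chr11	55700000	135006516	q11	gneg
chr12	0	33300000	p11	gneg
chr12	33300000	35800000	p11.1	acen
chr12	35800000	38200000	q11.1	acen
chr12	38200000	133851895	q11	gneg
chr13	0	16300000	p11	gneg
chr13	16300000	17900000	p11.1	acen
chr13	17900000	19500000	q11.1	acen
chr13	19500000	115169878	q11	gneg
chr14	0	16100000	p11	gneg
chr14	16100000	17600000	p11.1	acen
chr14	17600000	19100000	q11.1	acen
chr14	19100000	107349540	q11	gneg
chr15	0	15800000	p11	gneg
chr15	15800000	1.9e+07	p11.1	acen
chr15	1.9e+07	20700000	q11.1	acen
chr15	20700000	102531392	q11	gneg
chr16	0	34600000	p11	gneg
chr16	34600000	36600000	p11.1	acen
chr16	36600000	38600000	q11.1	acen
chr16	38600000	90354753	q11	gneg
chr17	0	22200000	p11	gneg
chr17	22200000	2.4e+07	p11.1	acen
chr17	2.4e+07	25800000	q11.1	acen
chr17	25800000	81195210	q11	gneg
chr18	0	15400000	p11	gneg
chr18	15400000	17200000	p11.1	acen
chr18	17200000	1.9e+07	q11.1	acen
chr18	1.9e+07	78077248	q11	gneg
chr19	0	24400000	p11	gneg
chr19	24400000	26500000	p11.1	acen
chr19	26500000	28600000	q11.1	acen
chr19	28600000	59128983	q11	gneg
chr20	0	25600000	p11	gneg
chr20	25600000	27500000	p11.1	acen
chr20	27500000	29400000	q11.1	acen
chr20	29400000	63025520	q11	gneg
chr21	0	10900000	p11	gneg
chr21	10900000	13200000	p11.1	acen
chr21	13200000	14300000	q11.1	acen
chr21	14300000	48129895	q11	gneg
chr22	0	12200000	p11	gneg
chr22	12200000	14700000	p11.1	acen
chr22	14700000	17900000	q11.1	acen
chr22	17900000	51304566	q11	gneg
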