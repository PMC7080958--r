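chr1	0	57500000	p11	gneg
chr1	57500000	60000000	p11.1	acen
chr1	60000000	62500000	q11.1	acen
chr1	62500000	120000000	q11	gneg
chr2	0	47500000	p11	gneg
chr2	47500000	50000000	p11.1	acen
chr2	50000000	52500000	q11.1	acen
chr2	52500000	100000000	q11	gneg
chr3	0	37500000	p11	gneg
chr3	37500000	40000000	p11.1	acen
chr3	40000000	42500000	q11.1	acen
chr3	42500000	80000000	q11	gneg
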