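1	15000000	17000000
1	40000000	42000000
1	80000000	81500000
1	105000000	106000000
2	10000000	11500000
2	35000000	36000000
2	70000000	71000000
2	90000000	91000000
3	3000000	4000000
3	18000000	19000000
3	55000000	56000000
3	70000000	71500000
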