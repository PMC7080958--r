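1	10000000	12000000
1	30500000	31500000
1	70000000	71000000
1	95000000	96500000
2	5000000	6000000
2	20000000	22000000
2	60000000	61000000
2	80500000	82000000
3	8000000	9000000
3	25000000	26500000
3	50000000	51000000
3	65000000	66000000
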