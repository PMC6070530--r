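index	lower_days	upper_days
1	42.00	63.00
2	63.00	70.00
3	70.00	91.00
4	91.00	112.00
5	112.00	168.00
6	168.00	266.00
7	266.00	401.76
8	401.76	584.40
9	584.40	1010.50
10	1010.50	1741.00
11	1741.00	4297.75
12	4297.75	7219.75
13	7219.75	14891.00
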