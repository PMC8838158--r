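label	N	L	R	V	A	/
N	496	0	0	1	2	1
L	0	492	0	7	1	0
R	1	0	488	7	4	0
V	2	1	2	486	7	2
A	4	0	16	16	464	0
/	1	0	0	3	1	495
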