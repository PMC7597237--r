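X	Y	Z	p
0	1	1	0.25
0	2	2	0.25
1	0	1	0.25
2	0	2	0.25
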