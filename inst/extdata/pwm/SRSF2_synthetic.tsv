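# threshold: 5.0
pos	A	C	G	T
1	-0.5	1.0	0.0	-1.0
2	1.0	-0.5	0.5	-1.0
3	-0.5	-0.5	1.0	-1.0
4	-0.5	1.0	-0.5	-1.5
5	1.0	0.0	-0.5	-1.0
6	-0.5	-0.5	1.0	-0.5
7	1.0	-0.5	0.5	-1.0
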