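# threshold: 5.0
pos	A	C	G	T
1	1.0	-0.5	0.0	-1.0
2	-0.5	1.0	-0.5	-1.0
3	1.0	-0.5	0.0	-1.0
4	-1.0	1.0	0.0	-0.5
5	-0.5	-1.0	1.0	-0.5
6	1.0	-0.5	0.0	-1.0
7	1.0	-0.5	-0.5	-1.0
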