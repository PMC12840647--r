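from	to	weight
A	C	1
A	G	2
A	T	1
C	A	1
C	G	1
C	T	2
G	A	2
G	C	1
G	T	1
T	A	1
T	C	2
T	G	1
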