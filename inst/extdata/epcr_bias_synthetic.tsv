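from	A	C	G	T
A	0	0.04	0.22	0.10
C	0.035	0	0.015	0.10
G	0.10	0.015	0	0.035
T	0.10	0.22	0.04	0
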