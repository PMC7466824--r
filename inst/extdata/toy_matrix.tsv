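	c1
e1	1
e2	0
e3	1
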