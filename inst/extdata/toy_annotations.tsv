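e1	t4
e2	t5
e2	t6
e3	t2
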