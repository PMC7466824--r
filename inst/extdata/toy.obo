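format-version: 1.2
ontology: toy

[Term]
id: t0
name: root process

[Term]
id: t1
name: branch one
is_a: t0 ! root process

[Term]
id: t2
name: branch two
is_a: t0 ! root process

[Term]
id: t3
name: branch three
is_a: t0 ! root process

[Term]
id: t4
name: leaf under one and two
is_a: t1 ! branch one
is_a: t2 ! branch two

[Term]
id: t5
name: leaf under two and three
is_a: t2 ! branch two
is_a: t3 ! branch three

[Term]
id: t6
name: leaf under three
is_a: t3 ! branch three
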