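sample	population	locality
a1	A	l1
a2	A	l1
b1	B	l2
b2	B	l2
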