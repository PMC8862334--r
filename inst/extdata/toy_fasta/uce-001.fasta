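>a1
AAGGCCTTAA
>a2
AAGGCCTTAT
>b1
AAGGTTTTAA
>b2
AAGGTTTTAA
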