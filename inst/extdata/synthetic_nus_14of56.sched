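0
1
2
3
4
6
8
9
13
16
20
24
29
37
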