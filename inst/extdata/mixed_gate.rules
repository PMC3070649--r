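INPUT: I
OUTPUT: C
A = I
B = not S
C = A and not B
S = I
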