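INPUT: I
OUTPUT: O
A = I
B = I
C = A and B
D = C or G
E = B and not F
F = not S
G = B
O = D or E
S = A
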