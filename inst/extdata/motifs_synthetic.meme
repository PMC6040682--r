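MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF esr_like
letter-probability matrix: alength= 4 w= 13
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000

MOTIF bzip_like
letter-probability matrix: alength= 4 w= 7
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000

MOTIF pax_like
letter-probability matrix: alength= 4 w= 11
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000

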