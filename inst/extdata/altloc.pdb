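ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  CB ASER A   1       2.009   1.420   0.000  0.60  0.00           C
ATOM      4  CB BSER A   1       2.109   1.520   0.100  0.40  0.00           C
ATOM      5  OG ASER A   1       3.409   1.500   0.000  0.60  0.00           O
ATOM      6  OG BSER A   1       3.509   1.600   0.100  0.40  0.00           O
HETATM    7  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O
END
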