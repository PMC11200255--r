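REMARK synthetic toy pocket fragment for examples and tests
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.980  -0.773  -1.210  1.00  0.00           C
ATOM      6  H   ALA A   1      -0.480  -0.860   0.000  1.00  0.00           H
ATOM      7  OG  SER A   2       4.500   2.000   1.000  1.00  0.00           O
ATOM      8  HG  SER A   2       4.900   2.700   1.500  1.00  0.00           H
HETATM    9  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O
HETATM   10  O   HOH A 102      -6.000   5.000   2.000  1.00  0.00           O
END
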