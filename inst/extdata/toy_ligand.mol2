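@<TRIPOS>MOLECULE
toy_ligand
 5 4 0 0 0
SMALL
USER_CHARGES
@<TRIPOS>ATOM
      1 C1          3.0000    0.5000    0.2000 C.3     1  LIG1        0.1200
      2 O1          4.4000    0.5000    0.2000 O.3     1  LIG1       -0.4200
      3 N1          2.3000   -0.7000    0.8000 N.3     1  LIG1       -0.3300
      4 C2          2.6000    1.9000   -0.4000 C.3     1  LIG1        0.0200
      5 C3          2.9000    2.1000   -1.9000 C.3     1  LIG1       -0.0100
@<TRIPOS>BOND
     1    1    2 1
     2    1    3 1
     3    1    4 1
     4    4    5 1
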