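toy_ligand
  synthetic toy ligand

  5  4  0  0  0  0  0  0  0  0999 V2000
    3.0000    0.5000    0.2000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.4000    0.5000    0.2000 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.3000   -0.7000    0.8000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.6000    1.9000   -0.4000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9000    2.1000   -1.9000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  1  3  1  0
  1  4  1  0
  4  5  1  0
M  END
> <PARTIAL_CHARGES>
0.12
-0.42
-0.33
0.02
-0.01

$$$$
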