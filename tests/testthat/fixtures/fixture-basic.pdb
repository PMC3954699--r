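REMARK   2 RESOLUTION.    1.80 ANGSTROMS.
HELIX    1 H01 ALA A    2  ALA A    4  1
SHEET    2 S02 1 ALA A   5  ALA A   5  0
ATOM      1  N   ASP A   1       1.500   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ASP A   1       2.000   0.000   0.000  1.00  0.00           C
ATOM      3  N   GLY A   2       3.500   0.000   0.000  1.00  0.00           N
ATOM      4  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C
ATOM      5  N   HIS A   3       5.500   0.000   0.000  1.00  0.00           N
ATOM      6  CA  HIS A   3       6.000   0.000   0.000  1.00  0.00           C
ATOM      7  N   SER A   4       7.500   0.000   0.000  1.00  0.00           N
ATOM      8  CA  SER A   4       8.000   0.000   0.000  1.00  0.00           C
ATOM      9  N   CYS A   5       9.500   0.000   0.000  1.00  0.00           N
ATOM     10  CA  CYS A   5      10.000   0.000   0.000  1.00  0.00           C
HETATM   11  O   HOH A 101       0.000   3.300   0.000  1.00  0.00           O
HETATM   12  O   HOH A 102       0.000   4.400   0.000  1.00  0.00           O
END
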