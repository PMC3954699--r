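ATOM      1  CA  ALA A   1       0.000   0.000   1.000  1.00  0.00           C
ATOM      2  CA  ARG A   2       0.000   0.000   2.000  1.00  0.00           C
ATOM      3  CA  ASN A   3       0.000   0.000   3.000  1.00  0.00           C
ATOM      4  CA  ASP A   4       0.000   0.000   4.000  1.00  0.00           C
ATOM      5  CA  CYS A   5       0.000   0.000   5.000  1.00  0.00           C
ATOM      6  CA  GLN A   6       0.000   0.000   6.000  1.00  0.00           C
HETATM    7  CA  MSE A   7       0.000   0.000   7.000  1.00  0.00           C
ATOM      8  CA  GLY A   8       0.000   0.000   8.000  1.00  0.00           C
ATOM      9  CA  HIS A   9       0.000   0.000   9.000  1.00  0.00           C
ATOM     10  CA  ILE A  10       0.000   0.000  10.000  1.00  0.00           C
ATOM     11  CA  LEU A  11       0.000   0.000  11.000  1.00  0.00           C
ATOM     12  CA  LYS A  12       0.000   0.000  12.000  1.00  0.00           C
ATOM     13  CA  MET A  13       0.000   0.000  13.000  1.00  0.00           C
ATOM     14  CA  PHE A  14       0.000   0.000  14.000  1.00  0.00           C
END
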