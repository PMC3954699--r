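ATOM      1  N   ASP A  25      11.104   6.134  -6.504  1.00 10.00           N
ATOM      2  OD2AASP A  25       1.000   2.000   3.000  0.40 12.00           O
ATOM      3  OD2BASP A  25       1.100   2.100   3.100  0.60 12.00           O
ATOM      4  CA  ASP A  25      12.000   6.000  -6.000  1.00 10.00           C
END
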