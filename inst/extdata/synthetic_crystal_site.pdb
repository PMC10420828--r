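TITLE     synthetic cofactor-substrate contact site (not a deposited structure)
ATOM      1  CB  SAH A 702      -2.900   1.300   0.200  1.00  0.00           C
ATOM      2  CG  SAH A 702      -1.600   0.600   0.100  1.00  0.00           C
ATOM      3  SD  SAH A 702       0.000   0.000   0.000  1.00  0.00           S
ATOM      4  C5p SAH A 702      -0.800   1.400  -1.100  1.00  0.00           C
ATOM      5  C11 LGC A 801       4.420   0.400   0.000  1.00  0.00           C
ATOM      6  O1  LGC A 801       3.300   0.000   0.000  1.00  0.00           O
ATOM      7  O2  LGC A 801       5.300   1.200   0.000  1.00  0.00           O
ATOM      8  C7  LGC A 801       5.100  -0.700   0.900  1.00  0.00           C
ATOM      9  NE2 HIS A 162       1.200   3.100   0.800  1.00  0.00           N
ATOM     10  CA  HIS A 162      -0.900   4.200   1.500  1.00  0.00           C
END
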