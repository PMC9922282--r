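ATOM      1  N   PHE A  21       3.800   1.200   0.500  1.00  0.00           N
ATOM      2  CA  PHE A  21       3.800   2.400   0.500  1.00  0.00           C
ATOM      3  C   PHE A  21       3.800   3.600   0.500  1.00  0.00           C
ATOM      4  O   PHE A  21       3.800   4.800   0.500  1.00  0.00           O
ATOM      5  N   TYR A 116       7.600   1.200   1.000  1.00  0.00           N
ATOM      6  CA  TYR A 116       7.600   2.400   1.000  1.00  0.00           C
ATOM      7  C   TYR A 116       7.600   3.600   1.000  1.00  0.00           C
ATOM      8  O   TYR A 116       7.600   4.800   1.000  1.00  0.00           O
ATOM      9  N   LEU A 117      11.400   1.200   1.500  1.00  0.00           N
ATOM     10  CA  LEU A 117      11.400   2.400   1.500  1.00  0.00           C
ATOM     11  C   LEU A 117      11.400   3.600   1.500  1.00  0.00           C
ATOM     12  O   LEU A 117      11.400   4.800   1.500  1.00  0.00           O
ATOM     13  N   SER A 138      15.200   1.200   2.000  1.00  0.00           N
ATOM     14  CA  SER A 138      15.200   2.400   2.000  1.00  0.00           C
ATOM     15  C   SER A 138      15.200   3.600   2.000  1.00  0.00           C
ATOM     16  O   SER A 138      15.200   4.800   2.000  1.00  0.00           O
ATOM     17  N   TYR A 151      19.000   1.200   2.500  1.00  0.00           N
ATOM     18  CA  TYR A 151      19.000   2.400   2.500  1.00  0.00           C
ATOM     19  C   TYR A 151      19.000   3.600   2.500  1.00  0.00           C
ATOM     20  O   TYR A 151      19.000   4.800   2.500  1.00  0.00           O
ATOM     21  N   PHE A 185      22.800   1.200   3.000  1.00  0.00           N
ATOM     22  CA  PHE A 185      22.800   2.400   3.000  1.00  0.00           C
ATOM     23  C   PHE A 185      22.800   3.600   3.000  1.00  0.00           C
ATOM     24  O   PHE A 185      22.800   4.800   3.000  1.00  0.00           O
ATOM     25  N   ILE A 190      26.600   1.200   3.500  1.00  0.00           N
ATOM     26  CA  ILE A 190      26.600   2.400   3.500  1.00  0.00           C
ATOM     27  C   ILE A 190      26.600   3.600   3.500  1.00  0.00           C
ATOM     28  O   ILE A 190      26.600   4.800   3.500  1.00  0.00           O
ATOM     29  N   LEU A 191      30.400   1.200   4.000  1.00  0.00           N
ATOM     30  CA  LEU A 191      30.400   2.400   4.000  1.00  0.00           C
ATOM     31  C   LEU A 191      30.400   3.600   4.000  1.00  0.00           C
ATOM     32  O   LEU A 191      30.400   4.800   4.000  1.00  0.00           O
ATOM     33  N   TYR A 217      34.200   1.200   4.500  1.00  0.00           N
ATOM     34  CA  TYR A 217      34.200   2.400   4.500  1.00  0.00           C
ATOM     35  C   TYR A 217      34.200   3.600   4.500  1.00  0.00           C
ATOM     36  O   TYR A 217      34.200   4.800   4.500  1.00  0.00           O
ATOM     37  N   TYR A 256      38.000   1.200   5.000  1.00  0.00           N
ATOM     38  CA  TYR A 256      38.000   2.400   5.000  1.00  0.00           C
ATOM     39  C   TYR A 256      38.000   3.600   5.000  1.00  0.00           C
ATOM     40  O   TYR A 256      38.000   4.800   5.000  1.00  0.00           O
END
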