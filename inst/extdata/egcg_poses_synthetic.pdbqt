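MODEL 1
REMARK VINA RESULT:     -9.10      0.000      0.000
ROOT
ATOM      1  C1  LIG L   1       2.000   2.000   3.000  0.00  0.00     0.035 C 
ATOM      2  O1  LIG L   1       3.500   2.000   3.000  0.00  0.00    -0.350 OA
ENDROOT
TORSDOF 1
ENDMDL
MODEL 2
REMARK VINA RESULT:     -8.41      0.000      0.000
ROOT
ATOM      1  C1  LIG L   1       3.000   2.000   3.000  0.00  0.00     0.035 C 
ATOM      2  O1  LIG L   1       4.500   2.000   3.000  0.00  0.00    -0.350 OA
ENDROOT
TORSDOF 1
ENDMDL
MODEL 3
REMARK VINA RESULT:     -7.95      0.000      0.000
ROOT
ATOM      1  C1  LIG L   1       4.000   2.000   3.000  0.00  0.00     0.035 C 
ATOM      2  O1  LIG L   1       5.500   2.000   3.000  0.00  0.00    -0.350 OA
ENDROOT
TORSDOF 1
ENDMDL
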