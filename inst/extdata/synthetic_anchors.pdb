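REMARK   1 SYNTHETIC six-anchor fixture with constructed coordinates:
REMARK   1 c=(0,0,1) b=(0,0,0) a=(1.5,0,0) A=(1.5,3,0) B=(3,3,0) C=(3,3,1.5)
REMARK   1 gives r=3.0 A, theta_A=theta_B=90 deg, phi_A=-90, phi_B=180, phi_C=-90.
REMARK   1 Serial 7 is a hydrogen (invalid anchor); serials 8/9 are an altloc
REMARK   1 pair (ambiguous unless the altloc is given).
ATOM      1  N   ALA A   1       0.000   0.000   1.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       1.500   0.000   0.000  1.00  0.00           C
HETATM    4  C1  LIG B   1       1.500   3.000   0.000  1.00  0.00           C
HETATM    5  C2  LIG B   1       3.000   3.000   0.000  1.00  0.00           C
HETATM    6  C3  LIG B   1       3.000   3.000   1.500  1.00  0.00           C
HETATM    7  H1  LIG B   1       1.500   3.500   0.500  1.00  0.00           H
HETATM    8  O1 ALIG B   1       3.500   2.500   1.500  0.50  0.00           O
HETATM    9  O1 BLIG B   1       3.600   2.400   1.600  0.50  0.00           O
END
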