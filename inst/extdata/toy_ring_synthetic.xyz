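12
synthetic benzene-like ring, 6C ring (atoms 1-6) + 6H
C      1.39000000     0.00000000     0.00000000
C      0.69500000     1.20377531     0.00000000
C     -0.69500000     1.20377531     0.00000000
C     -1.39000000     0.00000000     0.00000000
C     -0.69500000    -1.20377531     0.00000000
C      0.69500000    -1.20377531     0.00000000
H      2.47000000     0.00000000     0.00000000
H      1.23500000     2.13908275     0.00000000
H     -1.23500000     2.13908275     0.00000000
H     -2.47000000     0.00000000     0.00000000
H     -1.23500000    -2.13908275     0.00000000
H      1.23500000    -2.13908275     0.00000000
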