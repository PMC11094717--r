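# Benchmark restraint set EXTR (T = 300 K, 1 M standard state)
# Dihedral targets are zero: they cancel from every harmonic scheme.
label: EXTR
temperature: 300
standard_concentration: 1
K_r: 1.0
r0: 3.00
K_theta: 1.0
theta_A0: 22.50
theta_B0: 157.50
K_phi: 1.0
phi_A0: 0
phi_B0: 0
phi_C0: 0
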