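# Benchmark restraint set L1A-F (T = 300 K, 1 M standard state)
# Dihedral targets are zero: they cancel from every harmonic scheme.
label: L1A-F
temperature: 300
standard_concentration: 1
K_r: 4.0
r0: 5.10
K_theta: 8.0
theta_A0: 67.50
theta_B0: 84.50
K_phi: 5.0
phi_A0: 0
phi_B0: 0
phi_C0: 0
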