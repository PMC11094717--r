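# Benchmark restraint set CL1/SCH (T = 300 K, 1 M standard state)
# Dihedral targets are zero: they cancel from every harmonic scheme.
label: CL1/SCH
temperature: 300
standard_concentration: 1
K_r: 1.0
r0: 3.48
K_theta: 40.0
theta_A0: 89.73
theta_B0: 124.14
K_phi: 40.0
phi_A0: 0
phi_B0: 0
phi_C0: 0
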