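Package: vbarest
Title: Standard-State Restraint Free-Energy Corrections for Absolute
    Binding Free Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical, exact and numerical evaluation of the restraint
    free-energy correction for the six-coordinate orientational restraint
    scheme (one distance, two angles, three dihedrals; the "virtual bond
    algorithm") used in double-decoupling absolute binding free energy
    calculations. Implements the rigid-rotator harmonic-oscillator closed
    forms, the more rigorous closed forms with true Jacobians and
    integration limits, the fully exact angle configurational integral via
    complex-argument error functions, and adaptive numerical quadrature
    (the only route supporting flat-bottom restraints), together with the
    standard-state conversion to a free energy, restraint-safety
    diagnostics, and measurement of restraint targets from a PDB
    structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
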