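---
title: "Restraint free-energy corrections: models, schemes and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint free-energy corrections: models, schemes and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbarest)
```

## The problem

In a double-decoupling absolute binding free energy (ABFE) calculation the
ligand's interactions with its environment are switched off while a set of
restraints holds it in a bound-like position and orientation. The
free-energy cost of those restraints — the difference between the
restrained, decoupled ligand and a freely moving ligand at standard
concentration — must be added analytically. For the six-coordinate
"virtual bond algorithm" (VBA) scheme (one distance $r$, two angles
$\theta_A, \theta_B$, three dihedrals $\phi_A, \phi_B, \phi_C$, defined on
three receptor anchors c, b, a and three ligand anchors A, B, C), the
restrained external degrees of freedom contribute a configurational
integral that factorizes into six one-dimensional integrals,

$$Z_{rest} = \prod_{i=1}^{6} Z_i, \qquad
  Z_i = \int |J_i(x)|\, e^{-\beta K_i (x - x_{i,0})^2}\, dx ,$$

with Jacobians $|J_r| = r^2$, $|J_\theta| = \sin\theta$, $|J_\phi| = 1$,
and limits $(0,\infty)$, $(0,\pi)$ and $(\phi_0 - \pi, \phi_0 + \pi)$
respectively. The correction then reads

$$\Delta A_{rest} = -kT \ln \frac{8\pi^2 V_0}{Z_{rest}},$$

where $8\pi^2 V_0$ is the external-degrees-of-freedom factor of an
unrestrained molecule at the standard-state volume
$V_0 = 10^{27} / (N_A c_0)\ \mathrm{\AA^3}$ (about 1660 Å³ at 1 mol/L).
The package reports $\Delta A_{rest}$ in the restraint-formation direction
(typical sets give negative values); `direction = "removal"` negates it
for the opposite bookkeeping convention.

Note the potential convention: $U = K(x - x_0)^2$ with **no** factor
$\tfrac12$, so $K = 1$ kcal/(mol Å²) prices a 1 Å displacement at exactly
1 kcal/mol. Engines that define $U = \tfrac12 k x^2$ should pass
`half_factor = TRUE` (or set it in the config file), which halves $k$ on
input.

## The four evaluation schemes

1. **RRHO** (`z_rest_rrho()`). Two approximations make every factor a pure
   Gaussian: (A1) the Jacobian is frozen at the target — the rigid-rotator
   step — and (A2) the limits are extended to $\pm\infty$ — the
   harmonic-oscillator step. Each factor becomes
   $|J(x_0)| \sqrt{\pi kT / K}$, so the dihedral targets cancel entirely.
2. **Rigorous closed forms** (`z_rest_chen()`). The distance factor is
   integrated over its true domain $(0, \infty)$ with $r^2$ inside the
   integral; the dihedral over its full period, giving an
   $\mathrm{erf}(\pi\sqrt{\beta K})$ factor; the angle keeps
   $\sin\theta$ inside the integral but still extends the limits to
   $\pm\infty$, giving $\sin\theta_0\sqrt{\pi/\beta K}\,e^{-1/(4\beta K)}$.
3. **Exact** (`z_rest_exact()`). As (2), but the angle integral is
   evaluated on $(0,\pi)$ exactly, via error functions of complex
   argument (below). Distance and dihedral factors are shared with (2):
   those already use true limits and Jacobians.
4. **Numerical quadrature** (`z_rest_numeric()`). Adaptive quadrature of
   each defining integral. This is the only scheme that accepts
   flat-bottom potentials ($U = 0$ within a half-width $w$ of the target,
   harmonic beyond), and at its default tolerances it doubles as the
   reference the analytic schemes are validated against.

`compare_schemes()` evaluates all four and the pairwise gaps
$\delta\Delta A = kT\ln(Z^{approx}/Z^{ref})$; `cmd_table1()` does so for
the five bundled benchmark sets.

## The exact angle integral

Writing $a = \beta K$ and
$\sin\theta = (e^{i\theta} - e^{-i\theta})/2i$, completing the square in
each half gives

$$Z_\theta = \frac{\sqrt{\pi}}{2\sqrt{a}}\, \frac{e^{-1/(4a)}}{2i}
  \left[e^{i\theta_0} E_- - e^{-i\theta_0} E_+\right],\quad
  E_\pm = \mathrm{erf}\!\Big(\sqrt{a}(\pi - \theta_0) \pm \tfrac{i}{2\sqrt a}\Big)
        - \mathrm{erf}\!\Big(-\sqrt{a}\,\theta_0 \pm \tfrac{i}{2\sqrt a}\Big).$$

The two bracketed terms are complex conjugates analytically, so the result
is real. The implementation evaluates them independently (so conjugate
symmetry is a genuine check rather than an identity of the code path),
asserts that the residual imaginary part is below $10^{-12}$ of the real
part, and returns the real part; a violation raises an error directing the
caller to quadrature. The complex error function comes from
`pracma::erfz`, guarded by an asymptotic cutoff: for arguments with
$x^2 - y^2 > 700$ the function is $\mathrm{sign}(x)$ up to a remainder
below $e^{-700}$, which avoids exercising the series far out on the real
axis where it is wasteful and eventually inaccurate. With this guard the
route is stable at least to $K = 10^5$ kcal/(mol rad²); all closed forms
are additionally accumulated in log space at the set level so stiff
restraints cannot underflow.

Because the closed forms are derived here rather than transcribed, the
binding contract in the test suite is *oracle equality*: every analytic
factor must match adaptive Gauss–Kronrod quadrature (`pracma::quadgk`, a
code path independent of the `stats::integrate` engine the quadrature
scheme uses) to $10^{-8}$ relative or better over randomized safe
parameter draws ($K \in [0.5, 100]$, $r_0 \in [2, 8]$ Å, $\theta_0 \in
[20^\circ, 160^\circ]$) and on the five bundled sets.

## Numerical choices

* **Quadrature tolerances.** `rel_tol = 1e-10`, `abs_tol = 1e-14` by
  default — far beyond the ±0.1 kcal/mol that matters physically, so the
  scheme can serve as a reference.
* **Domain truncation.** Each integral is evaluated on the intersection of
  its true domain with a ±20σ window about the target
  (σ = $\sqrt{kT/2K}$, widened by $w$ for flat bottoms). The Boltzmann
  factor at the window edge is $e^{-200}$, so the neglected tail is below
  $10^{-15}$ of the result; the code asserts this bound rather than
  assuming it. The window also keeps the adaptive subdivision anchored on
  the peak for very stiff restraints, where quadrature over the full
  $(0,\pi)$ domain could miss a narrow integrand entirely.
* **Flat-bottom splitting.** The integrand has a derivative discontinuity
  at the well edges $x_0 \pm w$; the integration interval is split there
  so no panel straddles it.
* **Degenerate geometry.** Dihedral measurement uses the atan2 convention
  (cis = 0°, sign by the right-hand rule about the central bond, range
  (−180°, 180°]) and raises a named error when three consecutive anchors
  are collinear. Dihedral displacements in the potential are wrapped into
  (−π, π] so the energy is periodic.

## Safety diagnostics

Angle restraints must keep instantaneous values away from 0 and 180°,
where the $\sin\theta$ Jacobian vanishes and simulations become unstable;
a distance restraint must keep $r$ away from 0. `safety_report()` flags
any angle target within $n_\sigma \sigma$ (default 5) of a boundary and a
distance target within $5\sigma$ of zero — the generalization of the
argument that $r_0 = 3$ Å at $K = 1$ kcal/(mol Å²), 300 K is safe because
3 Å exceeds $5\sigma \approx 2.75$ Å. The margin is deliberately
conservative: the moderately soft L1A-5 set trips the angle warning by a
fraction of a degree, while the stiff CL1 set is clean and the EXTR set
(targets 22.5°/157.5° at $K = 1$) is flagged on both angles, as it should
be. The threshold is a diagnostic, not a gate: computation proceeds
regardless.

## Bundled benchmark sets and what they show

Five restraint sets ship as config fixtures (300 K, 1 M): `L1A-5`,
`L1A-F` (moderate force constants), `CL1` (stiff), `CL1/SCH` (CL1 targets
with a soft $K_r = 1$ distance restraint and $K = 40$ angles/dihedrals)
and `EXTR` (everything at $K = 1$ with angle targets 22.5°/157.5°,
deliberately unsafe, built to stress the approximations). Their dihedral
targets are stored as 0 since they cancel from every harmonic scheme. On
the four realistic sets the RRHO and rigorous schemes agree within
0.1 kcal/mol and the rigorous and exact schemes within 0.001 kcal/mol; on
EXTR the gap grows to about 0.16 kcal/mol, and the exact angle integral
lands *closer to the RRHO value than to the rigorous closed form* — the
two RRHO approximations partially cancel there, while extending the angle
limits with the Jacobian retained overshoots. Quadrature tracks the exact
scheme to well below 0.001 kcal/mol throughout, including EXTR. These are
exactly the numbers the test suite and `scripts/acceptance.R` recompute.

A useful rule of thumb falls out of the standard-state expression: holding
$|\delta\Delta A| \le 0.1$ kcal/mol at 300 K allows $Z_{rest}$ to be
overestimated by about 18% or underestimated by about 15.4%
(`tolerance_ratio_bounds(0.1)`) — configurational-integral errors are
heavily damped on the free-energy scale.

## What the tests do and do not show

The validation is purely against the mathematical contract: closed forms
versus independent quadrature, scheme-versus-scheme convergence in the
stiff limit ($K = 10^4$), importance-sampling cross-checks
($10^5$ Gaussian-proposal draws per coordinate, required to bracket
quadrature within three standard errors), and geometric invariances
(rigid motions preserve internals to $10^{-9}$; mirror reflection flips
dihedral signs). Problem sizes are small by construction — six
one-dimensional integrals per set, 100 randomized oracle draws, five
benchmark sets — because the quantities are desk-scale. None of this
says anything about whether VBA restraints are a *good choice* for a given
complex, whether the anchor atoms are well chosen, or how the restraint
free energy interacts with sampling error in the simulated legs of an
ABFE cycle; the package prices a given restraint set exactly, and the
safety report is the only judgment it passes on that set.

## Known limitations

* Closed forms cover harmonic potentials only; flat-bottom restraints go
  through quadrature (`compare_schemes()` then reports only that column).
* No anisotropic or multi-well restraints; no force-constant optimization;
  no trajectory averaging when seeding targets from a structure (the
  first PDB MODEL is used as-is; mmCIF is out of scope).
* The Monte-Carlo cross-check uses the Boltzmann Gaussian as its proposal
  and therefore supports harmonic restraints only.
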