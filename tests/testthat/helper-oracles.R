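# Independent oracles for the analytic and quadrature code paths.
#
# The package's own quadrature engine uses stats::integrate (QUADPACK
# QAGS); these helpers use pracma::quadgk (adaptive Gauss-Kronrod), a
# separate implementation, so closed forms, package quadrature and oracle
# quadrature are three independent routes.

# True configurational integral: Jacobian inside, true limits, truncated
# to a +/- 15 sigma window (Boltzmann factor exp(-112.5) at the edge).
oracle_z_true <- function(kind, K, x0, thermo = thermo_context(), w = 0) {
  beta <- thermo$beta
  sigma <- sqrt(thermo$kT / (2 * K))
  jac <- switch(kind, distance = function(x) x^2,
                angle = function(x) sin(x),
                dihedral = function(x) rep(1, length(x)))
  U <- function(x) {
    d <- pmax(abs(x - x0) - w, 0)
    K * d^2
  }
  limits <- switch(kind, distance = c(0, Inf), angle = c(0, pi),
                   dihedral = x0 + c(-pi, pi))
  lo <- max(limits[[1]], x0 - w - 15 * sigma)
  hi <- min(limits[[2]], x0 + w + 15 * sigma)
  pracma::quadgk(function(x) jac(x) * exp(-beta * U(x)), lo, hi, tol = 1e-13)
}

# Rigid-rotator harmonic-oscillator integrand: Jacobian frozen at the
# target, limits +/- 15 sigma (numerically +/- infinity).
oracle_z_rrho <- function(kind, K, x0, thermo = thermo_context()) {
  beta <- thermo$beta
  sigma <- sqrt(thermo$kT / (2 * K))
  j0 <- switch(kind, distance = x0^2, angle = sin(x0), dihedral = 1)
  pracma::quadgk(function(x) j0 * exp(-beta * K * (x - x0)^2),
                 x0 - 15 * sigma, x0 + 15 * sigma, tol = 1e-13)
}

# Alternative dihedral formula: project the outer bonds onto the plane
# normal to the central bond, angle between the projections, sign from the
# triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  b2h <- b2 / sqrt(sum(b2^2))
  u <- b1 - sum(b1 * b2h) * b2h
  v <- b3 - sum(b3 * b2h) * b2h
  cosphi <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  phi <- acos(max(-1, min(1, cosphi)))
  s <- sum(pracma::cross(u, v) * b2h)
  # -u (not u) spans the first half-plane in the torsion convention
  phi <- pi - phi
  if (s > 0) phi <- -phi
  if (phi <= -pi) phi <- phi + 2 * pi
  phi * 180 / pi
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

make_harmonic_set <- function(label = "test", K_r = 5, r0 = 4, K_theta = 10,
                              theta_A0 = 70, theta_B0 = 110, K_phi = 8,
                              phi0 = c(0, 0, 0)) {
  restraint_set(label,
    r = restraint("distance", K_r, r0),
    theta_A = restraint("angle", K_theta, theta_A0),
    theta_B = restraint("angle", K_theta, theta_B0),
    phi_A = restraint("dihedral", K_phi, phi0[[1]]),
    phi_B = restraint("dihedral", K_phi, phi0[[2]]),
    phi_C = restraint("dihedral", K_phi, phi0[[3]]))
}
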