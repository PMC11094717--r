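#' Rigid-rotator harmonic-oscillator configurational integrals
#'
#' Under two approximations the six configurational integrals of the VBA
#' restraints reduce to pure Gaussian integrals: (A1) the Jacobian of the
#' internal coordinate (r^2 for the distance, sin(theta) for an angle, 1
#' for a dihedral) is frozen at the restraint target and taken out of the
#' integral — the rigid-rotator step; (A2) the limits of integration are
#' extended to plus/minus infinity — the harmonic-oscillator step. Each
#' factor then evaluates in closed form:
#' \deqn{Z_r = r_0^2 \sqrt{\pi kT / K_r},\quad
#'       Z_\theta = \sin\theta_0 \sqrt{\pi kT / K_\theta},\quad
#'       Z_\phi = \sqrt{\pi kT / K_\phi}.}
#' The dihedral factor is independent of the target, which therefore
#' cancels from the whole scheme.
#'
#' @param K force constant, > 0.
#' @param r0 distance target in Angstrom, > 0.
#' @param theta0 angle target in radians, strictly inside (0, pi).
#' @param thermo a [thermo_context()].
#' @return the factor in A^3 (distance) or rad (angle, dihedral).
#' @name rrho_factors
NULL

# log of the Gaussian width integral sqrt(pi kT / K)
log_gauss_width <- function(K, thermo) 0.5 * (log(pi * thermo$kT) - log(K))

check_K <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("force constant must be a positive, finite number", call. = FALSE)
}

#' @rdname rrho_factors
#' @export
z_distance_rrho <- function(K, r0, thermo = thermo_context()) {
  check_K(K)
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("distance target r0 must be > 0 Angstrom", call. = FALSE)
  exp(2 * log(r0) + log_gauss_width(K, thermo))
}

#' @rdname rrho_factors
#' @export
z_angle_rrho <- function(K, theta0, thermo = thermo_context()) {
  check_K(K)
  if (!is.numeric(theta0) || length(theta0) != 1L ||
      theta0 <= 0 || theta0 >= pi)
    stop("angle target theta0 must lie strictly inside (0, pi) radians",
         call. = FALSE)
  exp(log(sin(theta0)) + log_gauss_width(K, thermo))
}

#' @rdname rrho_factors
#' @export
z_dihedral_rrho <- function(K, thermo = thermo_context()) {
  check_K(K)
  exp(log_gauss_width(K, thermo))
}

#' Rigid-rotator harmonic-oscillator partition of a restraint set
#'
#' Multiplies the six closed-form factors of [z_distance_rrho()],
#' [z_angle_rrho()] and [z_dihedral_rrho()] into Z_rest for the set. Only
#' harmonic restraints are supported; flat-bottom potentials need
#' [z_rest_numeric()].
#'
#' @param set a [restraint_set()].
#' @param thermo a [thermo_context()].
#' @return a [partition_result()] with scheme `"rrho"`.
#' @export
#' @examples
#' z <- z_rest_rrho(table1_sets("CL1")[[1]])
#' z$z_rest
z_rest_rrho <- function(set, thermo = thermo_context()) {
  stopifnot(inherits(set, "restraint_set"))
  stop_if_flat_bottom(set, "rrho")
  z <- c(
    r = z_distance_rrho(set$r$force_constant, set$r$target, thermo),
    theta_A = z_angle_rrho(set$theta_A$force_constant, set$theta_A$target, thermo),
    theta_B = z_angle_rrho(set$theta_B$force_constant, set$theta_B$target, thermo),
    phi_A = z_dihedral_rrho(set$phi_A$force_constant, thermo),
    phi_B = z_dihedral_rrho(set$phi_B$force_constant, thermo),
    phi_C = z_dihedral_rrho(set$phi_C$force_constant, thermo))
  partition_result("rrho", z, set$label)
}
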