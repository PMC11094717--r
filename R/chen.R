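#' Rigorous closed-form configurational integrals
#'
#' Closed forms for the per-coordinate configurational integrals that keep
#' the true Jacobian inside the integral and (for the distance and
#' dihedral) the true limits of integration, rather than applying the
#' rigid-rotator harmonic-oscillator approximations. Writing a = beta K:
#'
#' * distance, over (0, Inf) with Jacobian r^2:
#'   \deqn{Z_r = \left(r_0^2 + \tfrac{1}{2a}\right)
#'     \frac{\sqrt{\pi/a}}{2}\left(1 + \mathrm{erf}(r_0\sqrt{a})\right)
#'     + \frac{r_0}{2a} e^{-a r_0^2}}
#' * angle, over (-Inf, Inf) with Jacobian sin(theta) retained inside the
#'   integral (the one remaining approximation of this scheme is the
#'   extension of the (0, pi) limits):
#'   \deqn{Z_\theta = \sin\theta_0 \sqrt{\pi/a}\, e^{-1/(4a)}}
#' * dihedral, over the full period (phi_0 - pi, phi_0 + pi):
#'   \deqn{Z_\phi = \sqrt{\pi/a}\;\mathrm{erf}(\pi\sqrt{a})}
#'
#' Each form was derived by elementary Gaussian integration and is pinned
#' to adaptive quadrature of its defining integral in the test suite. The
#' angle factor equals its rigid-rotator counterpart times
#' exp(-1/(4 beta K)); the dihedral factor is always strictly below the
#' rigid-rotator value because erf(x) < 1.
#'
#' @inheritParams rrho_factors
#' @return the factor in A^3 (distance) or rad (angle, dihedral).
#' @name chen_factors
NULL

#' @rdname chen_factors
#' @export
z_distance_chen <- function(K, r0, thermo = thermo_context()) {
  check_K(K)
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("distance target r0 must be > 0 Angstrom", call. = FALSE)
  a <- thermo$beta * K
  (r0^2 + 1 / (2 * a)) * (sqrt(pi / a) / 2) * (1 + pracma::erf(r0 * sqrt(a))) +
    r0 * exp(-a * r0^2) / (2 * a)
}

#' @rdname chen_factors
#' @export
z_angle_chen <- function(K, theta0, thermo = thermo_context()) {
  check_K(K)
  if (!is.numeric(theta0) || length(theta0) != 1L ||
      theta0 <= 0 || theta0 >= pi)
    stop("angle target theta0 must lie strictly inside (0, pi) radians",
         call. = FALSE)
  a <- thermo$beta * K
  sin(theta0) * sqrt(pi / a) * exp(-1 / (4 * a))
}

#' @rdname chen_factors
#' @export
z_dihedral_chen <- function(K, thermo = thermo_context()) {
  check_K(K)
  a <- thermo$beta * K
  sqrt(pi / a) * pracma::erf(pi * sqrt(a))
}

# Complex error function with an asymptotic guard: pracma::erfz evaluates a
# series/continued fraction that is wasteful (and eventually inaccurate) far
# out on the real axis, where erf(z) = sign(Re z) up to a remainder bounded
# by exp(-(x^2 - y^2)) / (|x| sqrt(pi)). All arguments produced here have
# |Im z| = 1/(2 sqrt(a)) < 1, so x^2 - y^2 > 700 makes the remainder
# negligible at double precision.
erfz_safe <- function(z) {
  x <- Re(z); y <- Im(z)
  if (x^2 - y^2 > 700) return(complex(real = sign(x), imaginary = 0))
  pracma::erfz(z)
}

#' Exact angle configurational integral
#'
#' Evaluates \deqn{Z_\theta = \int_0^{\pi} \sin\theta\,
#'   e^{-\beta K (\theta - \theta_0)^2}\, d\theta} in closed form, with no
#' approximation: neither the Jacobian freeze nor the extension of the
#' integration limits. Writing sin(theta) = (e^{i theta} - e^{-i theta})/2i
#' and completing the square gives a combination of error functions of
#' complex argument,
#' \deqn{Z_\theta = \frac{\sqrt{\pi}}{2\sqrt{a}} \frac{e^{-1/(4a)}}{2i}
#'   \left[ e^{i\theta_0} E_- - e^{-i\theta_0} E_+ \right],\quad
#'   E_\pm = \mathrm{erf}\!\big(\sqrt{a}(\pi-\theta_0) \pm \tfrac{i}{2\sqrt{a}}\big)
#'         - \mathrm{erf}\!\big(-\sqrt{a}\,\theta_0 \pm \tfrac{i}{2\sqrt{a}}\big)}
#' with a = beta K. The result is real; the two bracketed terms are
#' conjugates analytically but are evaluated independently, and the
#' residual imaginary part is asserted to be below 1e-12 of the real part
#' before the real part is returned.
#'
#' @inheritParams rrho_factors
#' @return the angle factor in rad.
#' @export
z_angle_exact <- function(K, theta0, thermo = thermo_context()) {
  check_K(K)
  if (!is.numeric(theta0) || length(theta0) != 1L ||
      theta0 <= 0 || theta0 >= pi)
    stop("angle target theta0 must lie strictly inside (0, pi) radians",
         call. = FALSE)
  a <- thermo$beta * K
  sa <- sqrt(a)
  c <- 1 / (2 * sa)
  e_minus <- erfz_safe(complex(real = sa * (pi - theta0), imaginary = -c)) -
    erfz_safe(complex(real = -sa * theta0, imaginary = -c))
  e_plus <- erfz_safe(complex(real = sa * (pi - theta0), imaginary = c)) -
    erfz_safe(complex(real = -sa * theta0, imaginary = c))
  val <- (sqrt(pi) / (2 * sa)) * exp(-1 / (4 * a)) *
    (exp(1i * theta0) * e_minus - exp(-1i * theta0) * e_plus) / (2i)
  if (abs(Im(val)) > 1e-12 * abs(Re(val)) + 1e-300)
    stop(sprintf(paste0("exact angle integral is numerically unstable ",
                        "(residual imaginary part %.3g vs real part %.3g); ",
                        "fall back to quadrature"), Im(val), Re(val)),
         call. = FALSE)
  Re(val)
}

z_rest_analytic <- function(set, thermo, scheme, angle_fun) {
  stopifnot(inherits(set, "restraint_set"))
  stop_if_flat_bottom(set, scheme)
  z <- c(
    r = z_distance_chen(set$r$force_constant, set$r$target, thermo),
    theta_A = angle_fun(set$theta_A$force_constant, set$theta_A$target, thermo),
    theta_B = angle_fun(set$theta_B$force_constant, set$theta_B$target, thermo),
    phi_A = z_dihedral_chen(set$phi_A$force_constant, thermo),
    phi_B = z_dihedral_chen(set$phi_B$force_constant, thermo),
    phi_C = z_dihedral_chen(set$phi_C$force_constant, thermo))
  partition_result(scheme, z, set$label)
}

#' Rigorous and exact partitions of a restraint set
#'
#' `z_rest_chen()` multiplies the closed forms of [z_distance_chen()],
#' [z_angle_chen()] and [z_dihedral_chen()]. `z_rest_exact()` is identical
#' except that both angle factors use the fully exact (0, pi) integral
#' [z_angle_exact()]; the distance and dihedral factors already use their
#' true limits and Jacobians, so the two schemes share them.
#'
#' @param set a [restraint_set()] with six harmonic restraints.
#' @param thermo a [thermo_context()].
#' @return a [partition_result()] with scheme `"chen"` or `"exact"`.
#' @export
z_rest_chen <- function(set, thermo = thermo_context()) {
  z_rest_analytic(set, thermo, "chen", z_angle_chen)
}

#' @rdname z_rest_chen
#' @export
z_rest_exact <- function(set, thermo = thermo_context()) {
  z_rest_analytic(set, thermo, "exact", z_angle_exact)
}
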