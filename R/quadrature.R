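#' Describe one configurational integral
#'
#' Pairs a [restraint()] with the Jacobian and integration limits its
#' coordinate carries — (0, Inf) with Jacobian r^2 for a distance,
#' (0, pi) with Jacobian sin(theta) for an angle, and one full period
#' (phi_0 - pi, phi_0 + pi) with unit Jacobian for a dihedral — plus the
#' accuracy requested from the adaptive integrator. The defaults are far
#' tighter than any physical need so that quadrature can serve as the
#' reference the analytic schemes are checked against.
#'
#' @param restraint a [restraint()].
#' @param rel_tol,abs_tol requested relative and absolute accuracy, > 0.
#' @return an object of class `"integral_spec"`.
#' @export
integral_spec <- function(restraint, rel_tol = 1e-10, abs_tol = 1e-14) {
  stopifnot(inherits(restraint, "restraint"))
  if (!is.numeric(rel_tol) || rel_tol <= 0 || !is.numeric(abs_tol) || abs_tol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  limits <- switch(restraint$kind,
    distance = c(0, Inf),
    angle = c(0, pi),
    dihedral = restraint$target + c(-pi, pi))
  structure(
    list(restraint = restraint, lower = limits[[1]], upper = limits[[2]],
         rel_tol = rel_tol, abs_tol = abs_tol),
    class = "integral_spec")
}

jacobian_fun <- function(kind) {
  switch(kind,
         distance = function(x) x^2,
         angle = function(x) sin(x),
         dihedral = function(x) rep(1, length(x)))
}

#' Adaptive quadrature of one configurational integral
#'
#' Integrates Jacobian(x) * exp(-beta U(x)) over the coordinate's domain
#' with adaptive Gauss-Kronrod quadrature ([stats::integrate]). The domain
#' is intersected with a window of 20 thermal widths about the target
#' (widened by the flat-bottom half width where applicable): the Boltzmann
#' factor at the window edge is exp(-200), so the neglected tail is below
#' 1e-15 of the result by a Gaussian tail bound, which the function asserts.
#' Flat-bottom integrands are split at the well edges x0 +/- w so the
#' integrator never straddles the derivative discontinuity.
#'
#' @param spec an [integral_spec()].
#' @param thermo a [thermo_context()].
#' @return a list with `value` (the integral, A^3 or rad) and `abs_error`
#'   (the integrator's achieved-error estimate).
#' @export
integrate_spec <- function(spec, thermo = thermo_context()) {
  stopifnot(inherits(spec, "integral_spec"))
  rst <- spec$restraint
  jac <- jacobian_fun(rst$kind)
  f <- function(x) jac(x) * exp(-thermo$beta * potential_energy(rst, x))

  sigma <- thermal_sigma(rst$force_constant, thermo)
  w <- if (rst$potential_form == "flat_bottom") rst$half_width else 0
  # 20-sigma truncation: beta*K*(20 sigma)^2 = 200, so the Boltzmann factor
  # at the window edge is exp(-200) ~ 1.4e-87 and the neglected tail mass is
  # far below 1e-15 of the peak contribution.
  stopifnot(exp(-thermo$beta * rst$force_constant * (20 * sigma)^2) < 1e-60)
  lo <- max(spec$lower, rst$target - w - 20 * sigma)
  hi <- min(spec$upper, rst$target + w + 20 * sigma)
  if (lo >= hi)
    stop("empty integration window; target outside the coordinate domain",
         call. = FALSE)

  breaks <- sort(unique(c(lo, hi,
                          if (w > 0) pmin(pmax(rst$target + c(-w, w), lo), hi))))
  value <- 0
  abs_error <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    piece <- tryCatch(
      stats::integrate(f, breaks[[i]], breaks[[i + 1L]],
                       rel.tol = spec$rel_tol, abs.tol = spec$abs_tol,
                       subdivisions = 500L),
      error = function(e) e)
    if (inherits(piece, "error") || piece$message != "OK") {
      msg <- if (inherits(piece, "error")) conditionMessage(piece) else
        sprintf("%s (best estimate %.8g +/- %.2g)",
                piece$message, piece$value, piece$abs.error)
      stop(sprintf("quadrature failed for the %s coordinate: %s",
                   rst$kind, msg), call. = FALSE)
    }
    value <- value + piece$value
    abs_error <- abs_error + piece$abs.error
  }
  list(value = value, abs_error = abs_error)
}

#' Numerical-quadrature partition of a restraint set
#'
#' Evaluates all six configurational integrals by adaptive quadrature.
#' This is the only scheme that accepts flat-bottom restraints (for which
#' no closed form is implemented), and, at the default tolerances, the
#' reference the analytic schemes are compared against.
#'
#' @param set a [restraint_set()]; any mix of harmonic and flat-bottom.
#' @param thermo a [thermo_context()].
#' @param rel_tol,abs_tol forwarded to [integral_spec()].
#' @return a [partition_result()] with scheme `"quadrature"`.
#' @export
#' @examples
#' z_rest_numeric(table1_sets("EXTR")[[1]])
z_rest_numeric <- function(set, thermo = thermo_context(),
                           rel_tol = 1e-10, abs_tol = 1e-14) {
  stopifnot(inherits(set, "restraint_set"))
  z <- vapply(coordinate_slots(), function(nm) {
    tryCatch(
      integrate_spec(integral_spec(set[[nm]], rel_tol, abs_tol), thermo)$value,
      error = function(e) stop(sprintf("coordinate %s: %s", nm,
                                       conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  partition_result("quadrature", z, set$label)
}
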