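#' Thermodynamic context
#'
#' Bundles the temperature, Boltzmann constant and standard concentration
#' together with the derived quantities used everywhere downstream:
#' kT (kcal/mol), beta = 1/kT, and the standard-state volume V0 (A^3), the
#' volume available to one molecule at the reference concentration. At the
#' defaults (300 K, 1 mol/L) V0 is about 1660 A^3.
#'
#' @param temperature in Kelvin; default 300.
#' @param boltzmann_constant in kcal/(mol K); default 0.0019872041.
#' @param standard_concentration c0 in mol/L; default 1.
#' @return an object of class `"thermo"` with fields `temperature`,
#'   `boltzmann_constant`, `standard_concentration`, `kT`, `beta`, `V0`.
#' @export
#' @examples
#' th <- thermo_context()
#' th$V0    # ~1660.5 A^3
thermo_context <- function(temperature = 300,
                           boltzmann_constant = 0.0019872041,
                           standard_concentration = 1.0) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(boltzmann_constant), length(boltzmann_constant) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 K", call. = FALSE)
  if (boltzmann_constant <= 0)
    stop("boltzmann_constant must be > 0", call. = FALSE)
  kT <- boltzmann_constant * temperature
  structure(
    list(temperature = temperature,
         boltzmann_constant = boltzmann_constant,
         standard_concentration = standard_concentration,
         kT = kT, beta = 1 / kT,
         V0 = standard_volume(standard_concentration)),
    class = "thermo")
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf("<thermo> T = %g K, kT = %.6f kcal/mol, c0 = %g mol/L, V0 = %.2f A^3\n",
              x$temperature, x$kT, x$standard_concentration, x$V0))
  invisible(x)
}

AVOGADRO <- 6.02214076e23  # mol^-1 (2019 SI exact value)

#' Standard-state volume per molecule
#'
#' V0 = 1e27 / (N_A c0) Angstrom^3: the volume occupied per molecule at
#' concentration c0, with 1 L = 1e27 A^3. At c0 = 1 mol/L this is about
#' 1660 A^3, the factor that replaces the simulation-box volume when the
#' external degrees of freedom of an unrestrained ligand are referred to
#' the standard state.
#'
#' @param c0 standard concentration in mol/L, > 0.
#' @return volume in A^3.
#' @export
standard_volume <- function(c0) {
  stopifnot(is.numeric(c0), length(c0) == 1L)
  if (!is.finite(c0) || c0 <= 0)
    stop("standard concentration must be > 0 mol/L", call. = FALSE)
  1e27 / (AVOGADRO * c0)
}

#' Thermal width of a harmonic restraint
#'
#' The Boltzmann factor exp(-beta K (x - x0)^2), viewed (unnormalized) as a
#' Gaussian density, has standard deviation sigma = sqrt(kT / (2 K)). This
#' is the natural yardstick for how far a restrained coordinate fluctuates:
#' e.g. K = 1 kcal/(mol A^2) at 300 K gives sigma of about 0.55 A.
#'
#' @param K force constant, > 0 (kcal/(mol A^2) or kcal/(mol rad^2)).
#' @param thermo a [thermo_context()].
#' @return sigma in the coordinate's unit (A or rad).
#' @export
thermal_sigma <- function(K, thermo = thermo_context()) {
  stopifnot(is.numeric(K))
  if (any(!is.finite(K)) || any(K <= 0))
    stop("force constant must be > 0", call. = FALSE)
  sqrt(thermo$kT / (2 * K))
}

#' Restraint-safety diagnostics
#'
#' Angle restraints whose targets drift near 0 or 180 degrees make the
#' Jacobian sin(theta) vanish and destabilise simulations; a distance
#' target that can fluctuate to r = 0 is equally pathological. This check
#' flags any angle target within `n_sigma` thermal widths of 0 or pi, and a
#' distance target within `n_sigma` sigma of 0. The default margin of five
#' sigma generalizes the worked argument that r0 = 3 A with K = 1
#' kcal/(mol A^2) at 300 K is safe because 3 A exceeds 5 sigma ~ 2.75 A.
#'
#' @param set a [restraint_set()].
#' @param thermo a [thermo_context()].
#' @param n_sigma safety margin in units of sigma; default 5.
#' @return a data frame of class `"safety_report"` with columns
#'   `coordinate`, `margin` (distance to the nearest domain boundary, in the
#'   coordinate's unit), `sigma`, `message`; zero rows when the set is safe.
#' @export
safety_report <- function(set, thermo = thermo_context(), n_sigma = 5) {
  stopifnot(inherits(set, "restraint_set"))
  rows <- list()
  add <- function(coordinate, margin, sigma, message)
    rows[[length(rows) + 1L]] <<- data.frame(
      coordinate = coordinate, margin = margin, sigma = sigma,
      message = message, stringsAsFactors = FALSE)

  r <- set$r
  s <- thermal_sigma(r$force_constant, thermo)
  if (r$target < n_sigma * s)
    add("r", r$target, s, sprintf(
      "distance target %.2f A is within %g sigma (%.2f A) of r = 0", r$target,
      n_sigma, n_sigma * s))
  for (nm in c("theta_A", "theta_B")) {
    th <- set[[nm]]
    s <- thermal_sigma(th$force_constant, thermo)
    margin <- min(th$target, pi - th$target)
    if (margin < n_sigma * s)
      add(nm, margin, s, sprintf(
        "angle target %.2f deg is within %g sigma (%.2f deg) of 0 or 180 deg",
        rad2deg(th$target), n_sigma, rad2deg(n_sigma * s)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(coordinate = character(), margin = numeric(),
               sigma = numeric(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("safety_report", class(out))
  out
}

#' @export
print.safety_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("restraint set is safe: all targets clear their domain boundaries\n")
  } else {
    cat(sprintf("%d restraint-safety warning(s):\n", nrow(x)))
    for (m in x$message) cat("  - ", m, "\n", sep = "")
  }
  invisible(x)
}
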