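#' Angle unit conversion
#'
#' Degrees are the user-facing unit for angle and dihedral targets; all
#' internal computation is in radians.
#'
#' @param x numeric vector of angles.
#' @return numeric vector in the other unit.
#' @export
deg2rad <- function(x) x * (pi / 180)

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * (180 / pi)

#' Wrap a dihedral displacement into (-pi, pi]
#'
#' @param x displacement in radians.
#' @return wrapped displacement in (-pi, pi].
#' @export
wrap_dihedral <- function(x) {
  y <- x - 2 * pi * round(x / (2 * pi))
  # round() maps the boundary -pi to -pi; fold onto +pi for (-pi, pi]
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' Construct a single restraint term
#'
#' A restraint is one harmonic (or flat-bottomed) potential acting on a
#' single internal coordinate: the anchor-anchor distance r, one of the two
#' angles theta, or one of the three dihedrals phi. The potential is
#' \deqn{U(x) = K (x - x_0)^2} with no factor of 1/2 (so for a distance with
#' K = 1 kcal/(mol A^2), a 1 A displacement costs 1 kcal/mol). Engines using
#' the U = (1/2) k (x - x0)^2 convention should pass `half_factor = TRUE`,
#' which halves the supplied force constant on input.
#'
#' @param kind one of `"distance"`, `"angle"`, `"dihedral"`.
#' @param force_constant K, in kcal/(mol A^2) for a distance and
#'   kcal/(mol rad^2) for an angle or dihedral; must be > 0.
#' @param target x0: Angstrom for a distance (must be > 0); degrees for an
#'   angle (strictly inside (0, 180)) or dihedral (inside (-180, 180]).
#' @param potential_form `"harmonic"` or `"flat_bottom"`.
#' @param half_width flat-bottom half width w (>= 0), Angstrom or degrees to
#'   match `target`; `w = 0` makes the flat-bottom potential identical to
#'   the harmonic one. Ignored for `"harmonic"`.
#' @param half_factor if TRUE, `force_constant` is a 1/2-convention k and is
#'   divided by two on input.
#' @return an object of class `"restraint"`, storing the target (and half
#'   width) in internal units (Angstrom or radians).
#' @export
restraint <- function(kind = c("distance", "angle", "dihedral"),
                      force_constant,
                      target,
                      potential_form = c("harmonic", "flat_bottom"),
                      half_width = 0,
                      half_factor = FALSE) {
  kind <- match.arg(kind)
  potential_form <- match.arg(potential_form)
  stopifnot(is.numeric(force_constant), length(force_constant) == 1L,
            is.numeric(target), length(target) == 1L,
            is.numeric(half_width), length(half_width) == 1L)
  if (isTRUE(half_factor)) force_constant <- force_constant / 2
  if (!is.finite(force_constant) || force_constant <= 0)
    stop("force_constant must be a positive, finite number", call. = FALSE)
  if (half_width < 0)
    stop("half_width must be >= 0", call. = FALSE)
  if (kind == "distance") {
    if (target <= 0) stop("distance target must be > 0 Angstrom", call. = FALSE)
    x0 <- target
    w <- half_width
  } else if (kind == "angle") {
    if (target <= 0 || target >= 180)
      stop("angle target must lie strictly inside (0, 180) degrees", call. = FALSE)
    x0 <- deg2rad(target)
    w <- deg2rad(half_width)
  } else {
    if (target <= -180 || target > 180)
      stop("dihedral target must lie inside (-180, 180] degrees", call. = FALSE)
    x0 <- deg2rad(target)
    w <- deg2rad(half_width)
  }
  structure(
    list(kind = kind, force_constant = force_constant,
         target = x0, potential_form = potential_form, half_width = w),
    class = "restraint")
}

#' @export
print.restraint <- function(x, ...) {
  tgt <- if (x$kind == "distance") sprintf("%.3f A", x$target)
         else sprintf("%.2f deg", rad2deg(x$target))
  ku <- if (x$kind == "distance") "kcal/(mol A^2)" else "kcal/(mol rad^2)"
  cat(sprintf("<restraint> %s: K = %g %s, target = %s, %s",
              x$kind, x$force_constant, ku, tgt, x$potential_form))
  if (x$potential_form == "flat_bottom") {
    wu <- if (x$kind == "distance") sprintf("%.3f A", x$half_width)
          else sprintf("%.2f deg", rad2deg(x$half_width))
    cat(sprintf(" (w = %s)", wu))
  }
  cat("\n")
  invisible(x)
}

#' Assemble the six-restraint set of the virtual bond algorithm
#'
#' The VBA ties a ligand to its receptor through six internal coordinates
#' defined on three receptor anchors (c, b, a) and three ligand anchors
#' (A, B, C): the distance r = |a-A|, the angles theta_A (b-a-A) and
#' theta_B (a-A-B), and the dihedrals phi_A (c-b-a-A), phi_B (b-a-A-B) and
#' phi_C (a-A-B-C).
#'
#' @param label a short name for the set.
#' @param r distance [restraint].
#' @param theta_A,theta_B angle [restraint]s.
#' @param phi_A,phi_B,phi_C dihedral [restraint]s.
#' @return an object of class `"restraint_set"`.
#' @export
restraint_set <- function(label, r, theta_A, theta_B, phi_A, phi_B, phi_C) {
  stopifnot(is.character(label), length(label) == 1L)
  slots <- list(r = r, theta_A = theta_A, theta_B = theta_B,
                phi_A = phi_A, phi_B = phi_B, phi_C = phi_C)
  kinds <- c(r = "distance", theta_A = "angle", theta_B = "angle",
             phi_A = "dihedral", phi_B = "dihedral", phi_C = "dihedral")
  for (nm in names(slots)) {
    if (!inherits(slots[[nm]], "restraint"))
      stop(sprintf("slot '%s' must be a restraint object", nm), call. = FALSE)
    if (slots[[nm]]$kind != kinds[[nm]])
      stop(sprintf("slot '%s' must be a %s restraint, got %s",
                   nm, kinds[[nm]], slots[[nm]]$kind), call. = FALSE)
  }
  structure(c(list(label = label), slots), class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %s\n", x$label))
  for (nm in c("r", "theta_A", "theta_B", "phi_A", "phi_B", "phi_C")) {
    cat(sprintf("  %-8s ", nm)); print(x[[nm]])
  }
  invisible(x)
}

coordinate_slots <- function() c("r", "theta_A", "theta_B", "phi_A", "phi_B", "phi_C")

all_harmonic <- function(set) {
  all(vapply(coordinate_slots(),
             function(nm) set[[nm]]$potential_form == "harmonic" ||
               set[[nm]]$half_width == 0, logical(1)))
}

#' Restraint potential energy
#'
#' Evaluates U(x) for one restraint at a coordinate value given in internal
#' units (Angstrom for a distance, radians for an angle or dihedral). For
#' dihedrals, the displacement x - x0 is wrapped into (-pi, pi] first, so
#' the potential is periodic as the coordinate itself is.
#'
#' @param restraint a [restraint].
#' @param x coordinate value(s), Angstrom or radians.
#' @return potential energy in kcal/mol, vectorised over `x`.
#' @export
potential_energy <- function(restraint, x) {
  stopifnot(inherits(restraint, "restraint"))
  d <- x - restraint$target
  if (restraint$kind == "dihedral") d <- wrap_dihedral(d)
  d <- abs(d)
  if (restraint$potential_form == "flat_bottom") {
    d <- pmax(d - restraint$half_width, 0)
  }
  restraint$force_constant * d^2
}
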