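#' Per-coordinate configurational integrals and their product
#'
#' A `partition_result` holds the six one-dimensional configurational
#' integrals Z_i of a restraint set under one evaluation scheme, their
#' product Z_rest = Z_r Z_thetaA Z_thetaB Z_phiA Z_phiB Z_phiC
#' (units A^3 rad^5), and the log of that product. The product is
#' accumulated as a sum of logs so that very stiff restraints cannot
#' underflow.
#'
#' @param scheme one of `"rrho"`, `"chen"`, `"exact"`, `"quadrature"`.
#' @param z named numeric vector of the six factors, names
#'   `r`, `theta_A`, `theta_B`, `phi_A`, `phi_B`, `phi_C`, all > 0.
#' @param label restraint-set label the factors belong to.
#' @return an object of class `"partition_result"` with fields `scheme`,
#'   `label`, `z` (the six factors), `z_rest`, `log_z_rest`.
#' @export
partition_result <- function(scheme = c("rrho", "chen", "exact", "quadrature"),
                             z, label = "") {
  scheme <- match.arg(scheme)
  slots <- coordinate_slots()
  if (!is.numeric(z) || !setequal(names(z), slots))
    stop("z must be a numeric vector named r, theta_A, theta_B, phi_A, phi_B, phi_C",
         call. = FALSE)
  z <- z[slots]
  if (any(!is.finite(z)) || any(z <= 0))
    stop("all six configurational integrals must be finite and > 0", call. = FALSE)
  structure(
    list(scheme = scheme, label = label, z = z,
         z_rest = prod(z), log_z_rest = sum(log(z))),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %s scheme%s\n", x$scheme,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  units <- c(r = "A^3", theta_A = "rad", theta_B = "rad",
             phi_A = "rad", phi_B = "rad", phi_C = "rad")
  for (nm in names(x$z))
    cat(sprintf("  Z_%-8s = %.8g %s\n", nm, x$z[[nm]], units[[nm]]))
  cat(sprintf("  Z_rest     = %.8g A^3 rad^5\n", x$z_rest))
  invisible(x)
}

stop_if_flat_bottom <- function(set, scheme) {
  if (!all_harmonic(set))
    stop(sprintf(paste0("the %s scheme only supports harmonic restraints; ",
                        "use z_rest_numeric() for flat-bottom potentials"),
                 scheme), call. = FALSE)
}
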