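#' Standard-state restraint free energy
#'
#' Converts the restraint partition contribution Z_rest into the
#' free-energy correction
#' \deqn{\Delta A_{rest} = -kT \ln\!\frac{8\pi^2 V_0}{Z_{rest}},}
#' where 8 pi^2 V_0 is the contribution of the six external degrees of
#' freedom of an unrestrained molecule at the standard-state volume V0.
#' The default sign follows the restraint-formation direction (going from
#' the freely moving to the restrained ligand), under which typical
#' restraint sets give negative values; `direction = "removal"` negates
#' the result for the opposite bookkeeping used by some authors.
#'
#' @param z a [partition_result()].
#' @param thermo a [thermo_context()].
#' @param direction `"formation"` (default) or `"removal"`.
#' @return free energy in kcal/mol.
#' @export
#' @examples
#' delta_a_rest(z_rest_rrho(table1_sets("EXTR")[[1]]))  # about -5.74
delta_a_rest <- function(z, thermo = thermo_context(),
                         direction = c("formation", "removal")) {
  direction <- match.arg(direction)
  stopifnot(inherits(z, "partition_result"))
  if (!is.finite(z$z_rest) || z$z_rest <= 0)
    stop("Z_rest must be finite and > 0", call. = FALSE)
  dA <- -thermo$kT * (log(8 * pi^2 * thermo$V0) - z$log_z_rest)
  if (direction == "removal") -dA else dA
}

#' Free-energy error of an approximate partition
#'
#' The error incurred by replacing a reference Z_rest with an approximate
#' one is \deqn{\delta\Delta A = kT \ln(Z^{approx}_{rest} / Z^{ref}_{rest}),}
#' identically equal to the difference of the two [delta_a_rest()] values
#' (the standard-state factor cancels).
#'
#' @param z_approx,z_ref [partition_result()] objects under the same
#'   thermodynamic settings.
#' @param thermo a [thermo_context()].
#' @return signed error in kcal/mol.
#' @export
delta_delta_a <- function(z_approx, z_ref, thermo = thermo_context()) {
  stopifnot(inherits(z_approx, "partition_result"),
            inherits(z_ref, "partition_result"))
  thermo$kT * (z_approx$log_z_rest - z_ref$log_z_rest)
}

#' How wrong may Z_rest be for a given free-energy tolerance?
#'
#' If the restraint free energy is to be trusted to within
#' `delta_max` kcal/mol, the approximate Z_rest may exceed the true value
#' by a fraction exp(delta_max/kT) - 1 or fall short of it by
#' 1 - exp(-delta_max/kT). At 300 K and delta_max = 0.1 kcal/mol these
#' bounds are about +18% and -15.4%: configurational integrals are
#' forgiving on the free-energy scale.
#'
#' @param delta_max tolerated |delta Delta A| in kcal/mol, > 0.
#' @param thermo a [thermo_context()].
#' @return named numeric vector with components `excess` and `deficit`
#'   (fractions, not percent).
#' @export
tolerance_ratio_bounds <- function(delta_max, thermo = thermo_context()) {
  stopifnot(is.numeric(delta_max), length(delta_max) == 1L)
  if (!is.finite(delta_max) || delta_max <= 0)
    stop("delta_max must be > 0 kcal/mol", call. = FALSE)
  c(excess = exp(delta_max / thermo$kT) - 1,
    deficit = 1 - exp(-delta_max / thermo$kT))
}

#' Compare all evaluation schemes on one restraint set
#'
#' Computes the restraint free energy under the rigid-rotator
#' harmonic-oscillator, rigorous closed-form, exact and numerical
#' quadrature schemes, together with the pairwise deviations that quantify
#' each approximation. For a flat-bottom set only the quadrature column is
#' available and the analytic columns are NA.
#'
#' @param set a [restraint_set()].
#' @param thermo a [thermo_context()].
#' @return an object of class `"scheme_comparison"`: a list with the four
#'   free energies `dA_rrho`, `dA_chen`, `dA_exact`, `dA_numeric`
#'   (kcal/mol), the deltas `delta_rrho_vs_chen`, `delta_chen_vs_exact`,
#'   `delta_numeric_vs_exact`, the set `label` and the [safety_report()].
#' @export
compare_schemes <- function(set, thermo = thermo_context()) {
  stopifnot(inherits(set, "restraint_set"))
  z_nq <- z_rest_numeric(set, thermo)
  harmonic <- all_harmonic(set)
  if (harmonic) {
    z_rr <- z_rest_rrho(set, thermo)
    z_ch <- z_rest_chen(set, thermo)
    z_ex <- z_rest_exact(set, thermo)
    dA <- c(rrho = delta_a_rest(z_rr, thermo),
            chen = delta_a_rest(z_ch, thermo),
            exact = delta_a_rest(z_ex, thermo),
            numeric = delta_a_rest(z_nq, thermo))
    deltas <- c(delta_rrho_vs_chen = dA[["rrho"]] - dA[["chen"]],
                delta_chen_vs_exact = dA[["chen"]] - dA[["exact"]],
                delta_numeric_vs_exact = dA[["numeric"]] - dA[["exact"]])
  } else {
    dA <- c(rrho = NA_real_, chen = NA_real_, exact = NA_real_,
            numeric = delta_a_rest(z_nq, thermo))
    deltas <- c(delta_rrho_vs_chen = NA_real_, delta_chen_vs_exact = NA_real_,
                delta_numeric_vs_exact = NA_real_)
  }
  structure(
    list(label = set$label,
         dA_rrho = dA[["rrho"]], dA_chen = dA[["chen"]],
         dA_exact = dA[["exact"]], dA_numeric = dA[["numeric"]],
         delta_rrho_vs_chen = deltas[["delta_rrho_vs_chen"]],
         delta_chen_vs_exact = deltas[["delta_chen_vs_exact"]],
         delta_numeric_vs_exact = deltas[["delta_numeric_vs_exact"]],
         warnings = safety_report(set, thermo)),
    class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat(sprintf("<scheme_comparison> %s (kcal/mol, two decimals)\n", x$label))
  # two-decimal rendering for reports; underlying fields keep full precision
  fmt <- function(v) if (is.na(v)) "    NA" else sprintf("%6.2f", v)
  cat(sprintf("  dA_rrho = %s  dA_chen = %s  dA_exact = %s  dA_numeric = %s\n",
              fmt(x$dA_rrho), fmt(x$dA_chen), fmt(x$dA_exact), fmt(x$dA_numeric)))
  cat(sprintf("  rrho-chen = %s  chen-exact = %s  numeric-exact = %s\n",
              fmt(x$delta_rrho_vs_chen), fmt(x$delta_chen_vs_exact),
              fmt(x$delta_numeric_vs_exact)))
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}

#' Flatten scheme comparisons into a data frame
#'
#' @param comparisons a `scheme_comparison` or list of them.
#' @return one row per restraint set with full-precision numeric columns
#'   and a semicolon-joined `warnings` column.
#' @export
comparison_table <- function(comparisons) {
  if (inherits(comparisons, "scheme_comparison")) comparisons <- list(comparisons)
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(label = x$label, dA_rrho = x$dA_rrho, dA_chen = x$dA_chen,
               dA_exact = x$dA_exact, dA_numeric = x$dA_numeric,
               delta_rrho_vs_chen = x$delta_rrho_vs_chen,
               delta_chen_vs_exact = x$delta_chen_vs_exact,
               delta_numeric_vs_exact = x$delta_numeric_vs_exact,
               warnings = paste(x$warnings$message, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Monte-Carlo estimate of one configurational integral
#'
#' Importance sampling with the normalized Boltzmann Gaussian as proposal:
#' draws x ~ N(x0, sigma_B) with sigma_B = sqrt(kT/(2K)), weights each draw
#' by the Jacobian and the indicator of the coordinate's true domain, and
#' rescales by the Gaussian normalization sqrt(2 pi) sigma_B. A deliberately
#' crude, independent cross-check of the quadrature and closed-form routes;
#' harmonic restraints only.
#'
#' @param restraint a harmonic [restraint()].
#' @param thermo a [thermo_context()].
#' @param n number of draws.
#' @return list with `value`, `std_error`, `n`.
#' @export
z_mc_estimate <- function(restraint, thermo = thermo_context(), n = 1e5) {
  stopifnot(inherits(restraint, "restraint"))
  if (restraint$potential_form != "harmonic" && restraint$half_width > 0)
    stop("Monte-Carlo cross-check supports harmonic restraints only",
         call. = FALSE)
  sigma <- thermal_sigma(restraint$force_constant, thermo)
  x <- stats::rnorm(n, mean = restraint$target, sd = sigma)
  limits <- switch(restraint$kind,
    distance = c(0, Inf),
    angle = c(0, pi),
    dihedral = restraint$target + c(-pi, pi))
  w <- jacobian_fun(restraint$kind)(x) * (x >= limits[[1]] & x <= limits[[2]])
  scale <- sqrt(2 * pi) * sigma
  list(value = mean(w) * scale,
       std_error = stats::sd(w) / sqrt(n) * scale,
       n = n)
}

#' Write a scheme-comparison report
#'
#' TSV and JSON renderings contain the same full-precision numbers; the
#' two-decimal rounding is applied only by the print method.
#'
#' @param comparisons a `scheme_comparison` or list of them.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(comparisons, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- comparison_table(comparisons)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
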