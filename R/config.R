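#' Read a restraint-set configuration file
#'
#' The configuration is a flat YAML key/value file whose fields mirror the
#' columns of a restraint-parameter table: `K_r`, `r0`, `K_theta`,
#' `theta_A0`, `theta_B0`, `K_phi`, `phi_A0`, `phi_B0`, `phi_C0`, plus
#' `label`, `temperature` (K) and `standard_concentration` (mol/L).
#' Optional fields: `K_theta_A`/`K_theta_B` and `K_phi_A`/`K_phi_B`/
#' `K_phi_C` override the shared force constants; `potential_form`
#' (`harmonic`, the default, or `flat_bottom`) with `half_width_r` (A),
#' `half_width_theta` and `half_width_phi` (degrees); and
#' `half_factor: true` when the supplied force constants follow the
#' U = (1/2) k x^2 convention. Angles and dihedrals are in degrees.
#'
#' @param path file to read.
#' @return a list with components `set` (a [restraint_set()]) and `thermo`
#'   (a [thermo_context()]).
#' @export
read_restraint_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- c("label", "K_r", "r0", "theta_A0", "theta_B0")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop(sprintf("config %s: missing field(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  num <- function(field, default = NULL) {
    v <- cfg[[field]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("config %s: missing field '%s'", path, field), call. = FALSE)
      return(default)
    }
    if (!is.numeric(v) || length(v) != 1L)
      stop(sprintf("config %s: field '%s' must be a single number", path, field),
           call. = FALSE)
    as.numeric(v)  # YAML integers become doubles for bit-stable round trips
  }
  form <- cfg$potential_form %||% "harmonic"
  if (!form %in% c("harmonic", "flat_bottom"))
    stop(sprintf("config %s: unknown potential_form '%s'", path, form),
         call. = FALSE)
  hf <- isTRUE(cfg$half_factor)
  w_r <- num("half_width_r", 0)
  w_th <- num("half_width_theta", 0)
  w_ph <- num("half_width_phi", 0)
  K_theta <- if (!is.null(cfg$K_theta)) num("K_theta") else NULL
  K_phi <- if (!is.null(cfg$K_phi)) num("K_phi") else NULL
  kslot <- function(specific, shared, what) {
    if (!is.null(cfg[[specific]])) return(num(specific))
    if (!is.null(shared)) return(shared)
    stop(sprintf("config %s: no force constant for %s", path, what), call. = FALSE)
  }
  set <- restraint_set(
    label = as.character(cfg$label),
    r = restraint("distance", num("K_r"), num("r0"), form, w_r, hf),
    theta_A = restraint("angle", kslot("K_theta_A", K_theta, "theta_A"),
                        num("theta_A0"), form, w_th, hf),
    theta_B = restraint("angle", kslot("K_theta_B", K_theta, "theta_B"),
                        num("theta_B0"), form, w_th, hf),
    phi_A = restraint("dihedral", kslot("K_phi_A", K_phi, "phi_A"),
                      num("phi_A0", 0), form, w_ph, hf),
    phi_B = restraint("dihedral", kslot("K_phi_B", K_phi, "phi_B"),
                      num("phi_B0", 0), form, w_ph, hf),
    phi_C = restraint("dihedral", kslot("K_phi_C", K_phi, "phi_C"),
                      num("phi_C0", 0), form, w_ph, hf))
  thermo <- thermo_context(
    temperature = num("temperature", 300),
    standard_concentration = num("standard_concentration", 1))
  list(set = set, thermo = thermo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a restraint-set configuration file
#'
#' Inverse of [read_restraint_config()]. Numbers are written with 17
#' significant digits so that a write/read round trip reproduces every
#' field bit-identically.
#'
#' @param set a [restraint_set()].
#' @param thermo a [thermo_context()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_restraint_config <- function(set, thermo = thermo_context(), path) {
  stopifnot(inherits(set, "restraint_set"))
  fmt <- function(x) sprintf("%.17g", x)
  form <- set$r$potential_form
  lines <- c(
    sprintf("label: %s", set$label),
    sprintf("temperature: %s", fmt(thermo$temperature)),
    sprintf("standard_concentration: %s", fmt(thermo$standard_concentration)),
    sprintf("potential_form: %s", form),
    sprintf("K_r: %s", fmt(set$r$force_constant)),
    sprintf("r0: %s", fmt(set$r$target)),
    sprintf("K_theta_A: %s", fmt(set$theta_A$force_constant)),
    sprintf("K_theta_B: %s", fmt(set$theta_B$force_constant)),
    sprintf("theta_A0: %s", fmt(rad2deg(set$theta_A$target))),
    sprintf("theta_B0: %s", fmt(rad2deg(set$theta_B$target))),
    sprintf("K_phi_A: %s", fmt(set$phi_A$force_constant)),
    sprintf("K_phi_B: %s", fmt(set$phi_B$force_constant)),
    sprintf("K_phi_C: %s", fmt(set$phi_C$force_constant)),
    sprintf("phi_A0: %s", fmt(rad2deg(set$phi_A$target))),
    sprintf("phi_B0: %s", fmt(rad2deg(set$phi_B$target))),
    sprintf("phi_C0: %s", fmt(rad2deg(set$phi_C$target))))
  if (form == "flat_bottom")
    lines <- c(lines,
               sprintf("half_width_r: %s", fmt(set$r$half_width)),
               sprintf("half_width_theta: %s", fmt(rad2deg(set$theta_A$half_width))),
               sprintf("half_width_phi: %s", fmt(rad2deg(set$phi_A$half_width))))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled benchmark restraint sets
#'
#' Five restraint sets spanning realistic and deliberately pathological
#' parameter choices ship with the package as configuration fixtures:
#' `L1A-5` and `L1A-F` (moderate force constants), `CL1` (stiff, K = 20),
#' `CL1/SCH` (CL1 targets with a soft K_r = 1 distance restraint and stiff
#' K = 40 angles/dihedrals), and `EXTR` (all K = 1 with angle targets of
#' 22.5 and 157.5 degrees, built to stress the closed-form approximations).
#' Dihedral targets are zero throughout: they cancel from every harmonic
#' scheme.
#'
#' @param labels which sets to load; default all five.
#' @return a named list of [restraint_set()] objects.
#' @export
#' @examples
#' sets <- table1_sets()
#' names(sets)
table1_sets <- function(labels = c("L1A-5", "L1A-F", "CL1", "CL1/SCH", "EXTR")) {
  files <- c("L1A-5" = "L1A-5.yaml", "L1A-F" = "L1A-F.yaml",
             "CL1" = "CL1.yaml", "CL1/SCH" = "CL1-SCH.yaml",
             "EXTR" = "EXTR.yaml")
  unknown <- setdiff(labels, names(files))
  if (length(unknown))
    stop(sprintf("unknown restraint set(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  out <- lapply(labels, function(lab) {
    path <- system.file("extdata", files[[lab]], package = "vbarest",
                        mustWork = TRUE)
    read_restraint_config(path)$set
  })
  names(out) <- labels
  out
}
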