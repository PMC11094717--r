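vnorm <- function(v) sqrt(sum(v * v))

vec_angle <- function(u, v) {
  # arccos of the normalized dot product, clamped against rounding
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
}

# IUPAC torsion about the b2 = p3 - p2 bond: 0 at cis, sign by the
# right-hand rule, range (-pi, pi].
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("collinear atoms: dihedral undefined", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(pracma::cross(n1, n2) * b2) / vnorm(b2)
  phi <- atan2(y, x)
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

#' Measure the six VBA internal coordinates
#'
#' Given the Cartesian positions of the six anchor atoms in the order
#' c, b, a (receptor) then A, B, C (ligand), measures the distance
#' r = |a-A|, the angles theta_A (b-a-A) and theta_B (a-A-B) by the arccos
#' of normalized dot products, and the dihedrals phi_A (c-b-a-A),
#' phi_B (b-a-A-B), phi_C (a-A-B-C) by the atan2 convention (sign from the
#' scalar triple product; cis = 0, range (-180, 180]).
#'
#' @param coords a 6 x 3 numeric matrix, rows ordered c, b, a, A, B, C.
#' @return an object of class `"internal_coordinates"`: a named list with
#'   `r` (Angstrom) and `theta_A`, `theta_B`, `phi_A`, `phi_B`, `phi_C`
#'   (degrees).
#' @export
#' @examples
#' xyz <- rbind(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0),
#'              c(2, 0, 0), c(2, 1, 0), c(2, 1, 1))
#' measure_internals(xyz)
measure_internals <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !all(dim(coords) == c(6L, 3L)))
    stop("coords must be a 6 x 3 numeric matrix (rows c, b, a, A, B, C)",
         call. = FALSE)
  p <- lapply(seq_len(6), function(i) coords[i, ])
  names(p) <- c("c", "b", "a", "A", "B", "C")
  for (i in seq_len(5))
    if (vnorm(coords[i + 1L, ] - coords[i, ]) < 1e-10)
      stop("consecutive anchor atoms coincide", call. = FALSE)
  tors <- function(nm, q1, q2, q3, q4)
    tryCatch(torsion4(q1, q2, q3, q4),
             error = function(e) stop(sprintf("torsion %s: %s", nm,
                                              conditionMessage(e)), call. = FALSE))
  out <- list(
    r = vnorm(p$a - p$A),
    theta_A = rad2deg(vec_angle(p$b - p$a, p$A - p$a)),
    theta_B = rad2deg(vec_angle(p$a - p$A, p$B - p$A)),
    phi_A = rad2deg(tors("phi_A", p$c, p$b, p$a, p$A)),
    phi_B = rad2deg(tors("phi_B", p$b, p$a, p$A, p$B)),
    phi_C = rad2deg(tors("phi_C", p$a, p$A, p$B, p$C)))
  structure(out, class = "internal_coordinates")
}

#' @export
print.internal_coordinates <- function(x, ...) {
  cat(sprintf(paste0("<internal_coordinates> r = %.3f A, theta_A = %.2f, ",
                     "theta_B = %.2f, phi_A = %.2f, phi_B = %.2f, ",
                     "phi_C = %.2f deg\n"),
              x$r, x$theta_A, x$theta_B, x$phi_A, x$phi_B, x$phi_C))
  invisible(x)
}

# Resolve one anchor selector in a bio3d pdb object (first model only).
# Selectors: an atom serial number, or "chain:resno:atom_name" with an
# optional ":altloc" fourth field.
resolve_anchor <- function(pdb, selector) {
  atoms <- pdb$atom
  if (is.numeric(selector)) {
    idx <- which(atoms$eleno == selector)
    what <- sprintf("serial %g", selector)
  } else {
    parts <- strsplit(as.character(selector), ":", fixed = TRUE)[[1]]
    if (!length(parts) %in% c(3L, 4L))
      stop(sprintf("selector '%s' must be 'chain:resno:atom_name[:altloc]' or a serial number",
                   selector), call. = FALSE)
    idx <- which(atoms$chain == parts[[1]] &
                   atoms$resno == as.integer(parts[[2]]) &
                   atoms$elety == parts[[3]])
    if (length(parts) == 4L)
      idx <- idx[atoms$alt[idx] %in% parts[[4]]]
    what <- sprintf("selector '%s'", selector)
  }
  if (length(idx) == 0L)
    stop(sprintf("%s matches no atom in the structure", what), call. = FALSE)
  if (length(idx) > 1L)
    stop(sprintf("%s is ambiguous (%d atoms, check altloc)", what, length(idx)),
         call. = FALSE)
  idx
}

is_hydrogen <- function(atoms, idx) {
  elesy <- atoms$elesy[idx]
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy)))
    return(toupper(trimws(elesy)) == "H")
  grepl("^[0-9]*H", trimws(atoms$elety[idx]))
}

#' Build a restraint set from a structure
#'
#' Reads a PDB file (first MODEL only; ATOM and HETATM records are both
#' eligible), resolves the six anchor atoms c, b, a, A, B, C, measures the
#' six internal coordinates, and uses them as the restraint targets with
#' the supplied force constants. Hydrogens are rejected as anchors;
#' restraint-safety warnings for the resulting targets are attached.
#'
#' @param pdb_file path to a PDB file.
#' @param anchors list or vector of six selectors in the order c, b, a,
#'   A, B, C; each an atom serial number or a `"chain:resno:atom_name"`
#'   string (optionally `":altloc"`).
#' @param K_r,K_theta,K_phi force constants for the distance
#'   (kcal/(mol A^2)), angle and dihedral (kcal/(mol rad^2)) restraints.
#' @param thermo a [thermo_context()].
#' @param label label for the resulting set; defaults to the file name.
#' @return a list with `set` (a [restraint_set()]), `internals` (the
#'   measured [measure_internals()] values) and `warnings` (the
#'   [safety_report()]).
#' @export
restraint_set_from_structure <- function(pdb_file, anchors,
                                         K_r = 10, K_theta = 100, K_phi = 100,
                                         thermo = thermo_context(),
                                         label = NULL) {
  if (length(anchors) != 6L)
    stop("exactly six anchor selectors are required (c, b, a, A, B, C)",
         call. = FALSE)
  # keep all altloc records: ambiguity is resolved (or reported) per selector
  pdb <- bio3d::read.pdb(pdb_file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  idx <- vapply(seq_len(6), function(i) resolve_anchor(pdb, anchors[[i]]),
                integer(1))
  if (anyDuplicated(idx))
    stop("anchor selectors must resolve to six distinct atoms", call. = FALSE)
  hyd <- vapply(idx, function(i) is_hydrogen(pdb$atom, i), logical(1))
  if (any(hyd))
    stop(sprintf("hydrogen atoms cannot serve as anchors (position %s)",
                 paste(which(hyd), collapse = ", ")), call. = FALSE)
  coords <- as.matrix(pdb$atom[idx, c("x", "y", "z")])
  internals <- measure_internals(coords)
  set <- restraint_set(
    label = label %||% basename(pdb_file),
    r = restraint("distance", K_r, internals$r),
    theta_A = restraint("angle", K_theta, internals$theta_A),
    theta_B = restraint("angle", K_theta, internals$theta_B),
    phi_A = restraint("dihedral", K_phi, internals$phi_A),
    phi_B = restraint("dihedral", K_phi, internals$phi_B),
    phi_C = restraint("dihedral", K_phi, internals$phi_C))
  list(set = set, internals = internals,
       warnings = safety_report(set, thermo))
}
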