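#' Default ring-torsion atom quadruples for canthaxanthin
#'
#' The end-ring torsion of a carotenoid is the dihedral about the ring–chain
#' single bond (C6–C7 and the primed equivalent), measured over the
#' C5=C6–C7=C8 atoms. The chemical-component atom names used here follow the
#' standard carotenoid numbering; they can be overridden for ligands with
#' other naming schemes.
#'
#' @return Named list with `beta1` and `beta2`, each an ordered character
#'   vector of four atom names.
#' @export
default_quadruples <- function() {
  list(
    beta1 = c("C5", "C6", "C7", "C8"),
    beta2 = c("C5'", "C6'", "C7'", "C8'")
  )
}

#' Construct a chromophore geometry
#'
#' A light container for one carotenoid ligand: named 3D coordinates (Å),
#' the two ring-torsion atom quadruples, and the ordered conjugated-chain
#' (polyene) atom names used to define the transition-dipole axis.
#'
#' @param chain Chain identifier (single character).
#' @param resid Residue name (e.g. `"CAN"`).
#' @param coords Numeric matrix with 3 columns (x, y, z in Å) and atom names
#'   as row names.
#' @param quadruples List with `beta1` and `beta2` four-atom-name vectors; see
#'   [default_quadruples()].
#' @param polyene Ordered character vector (length >= 4) of conjugated-chain
#'   atom names, all present in `coords`.
#' @return A `chromophore_geometry` object.
#' @export
chromophore_geometry <- function(chain, resid, coords,
                                 quadruples = default_quadruples(),
                                 polyene) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, !is.null(rownames(coords)))
  if (any(!is.finite(coords))) {
    rlang::abort("coordinates must be finite.", class = "carospec_input_error")
  }
  missing <- setdiff(unique(unlist(quadruples)), rownames(coords))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("chromophore ", resid, " (chain ", chain,
             ") is missing ring-torsion atoms: ",
             paste(missing, collapse = ", ")),
      class = "carospec_incomplete_ligand"
    )
  }
  if (length(polyene) < 4 || !all(polyene %in% rownames(coords))) {
    rlang::abort("`polyene` needs >= 4 atom names, all present in `coords`.",
                 class = "carospec_input_error")
  }
  structure(
    list(chain = chain, resid = resid, coords = coords,
         quadruples = quadruples, polyene = polyene),
    class = "chromophore_geometry"
  )
}

#' @export
print.chromophore_geometry <- function(x, ...) {
  cat("<chromophore_geometry> ", x$resid, " chain ", x$chain, ": ",
      nrow(x$coords), " atoms, ", length(x$polyene), " polyene atoms\n",
      sep = "")
  invisible(x)
}

#' Load carotenoid ligands from a PDB file
#'
#' Reads a PDB file (first model only) and returns one geometry per matching
#' HETATM residue instance, resolved by chain. When alternate locations
#' exist, the highest-occupancy record is kept for each atom (first
#' alphabetical altloc on ties). Waters, ions and protein atoms are ignored.
#'
#' @param path Path to a PDB file.
#' @param residue Residue name to extract (default `"CAN"`, canthaxanthin).
#' @param quadruples Ring-torsion quadruples; see [default_quadruples()].
#' @param polyene Ordered polyene atom names; by default every atom named in
#'   the two quadruples plus all remaining `C`-element atoms between them, in
#'   file order, is used — for the idealized fixtures written by
#'   [write_fixture_pdb()] this is the full conjugated chain. Supply
#'   explicitly for real ligands.
#' @return List of [chromophore_geometry()] objects.
#' @export
read_chromophores <- function(path, residue = "CAN",
                              quadruples = default_quadruples(),
                              polyene = NULL) {
  stopifnot(nzchar(residue))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- dplyr::filter(atoms, .data$type == "HETATM", .data$resid == residue)
  if (nrow(atoms) == 0) {
    rlang::abort(paste0("no residue named '", residue, "' found in ", path),
                 class = "carospec_not_found")
  }
  atoms$o[is.na(atoms$o)] <- 1
  atoms$alt[is.na(atoms$alt)] <- ""
  groups <- dplyr::group_split(dplyr::group_by(atoms, .data$chain, .data$resno))
  purrr::map(groups, function(g) {
    # altloc policy: per atom name keep highest occupancy, then first altloc
    g <- dplyr::arrange(g, .data$elety, dplyr::desc(.data$o), .data$alt)
    g <- dplyr::distinct(g, .data$elety, .keep_all = TRUE)
    coords <- as.matrix(g[, c("x", "y", "z")])
    rownames(coords) <- g$elety
    poly <- polyene %||% infer_polyene(g$elety)
    chromophore_geometry(
      chain = g$chain[1], resid = residue, coords = coords,
      quadruples = quadruples, polyene = poly
    )
  })
}

# Polyene inference for idealized fixtures: chain carbons are every carbon
# that is not a terminal ring atom (C5, C6 and primed equivalents).
infer_polyene <- function(atom_names) {
  ring <- c("C1", "C2", "C3", "C4", "C5", "C6",
            "C1'", "C2'", "C3'", "C4'", "C5'", "C6'")
  poly <- atom_names[grepl("^C", atom_names) & !(atom_names %in% ring)]
  if (length(poly) < 4) poly <- atom_names[grepl("^C", atom_names)]
  poly
}

#' Signed torsion angle of four points
#'
#' Torsion of the p1–p2 bond against the p3–p4 bond viewed along p2→p3,
#' clockwise positive (the IUPAC convention), in degrees on (−180, 180].
#' Invariant under rigid rotation and translation; mirror reflection flips
#' the sign.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Å).
#' @return Signed dihedral in degrees.
#' @examples
#' compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180 (anti)
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    rlang::abort("torsion undefined: three consecutive points are collinear.",
                 class = "carospec_undefined_torsion")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' End-ring dihedrals of a chromophore
#'
#' Computes the two ring–chain torsions (phi1 from the beta1 quadruple, phi2
#' from beta2) of one carotenoid.
#'
#' @param geom A [chromophore_geometry()].
#' @return A one-row tibble: `chain`, `residue`, `phi1_deg`, `phi2_deg`.
#' @export
ring_dihedrals <- function(geom) {
  stopifnot(inherits(geom, "chromophore_geometry"))
  tor <- function(quad) {
    xyz <- geom$coords[quad, , drop = FALSE]
    compute_dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  }
  tibble::tibble(
    chain = geom$chain,
    residue = geom$resid,
    phi1_deg = tor(geom$quadruples$beta1),
    phi2_deg = tor(geom$quadruples$beta2)
  )
}

#' Extract end-ring dihedrals from a PDB file
#'
#' Convenience wrapper: [read_chromophores()] followed by [ring_dihedrals()]
#' for every ligand instance.
#'
#' @inheritParams read_chromophores
#' @return Tibble with one row per ligand: `chain`, `residue`, `phi1_deg`,
#'   `phi2_deg`.
#' @export
extract_dihedrals <- function(path, residue = "CAN",
                              quadruples = default_quadruples(),
                              polyene = NULL) {
  geoms <- read_chromophores(path, residue, quadruples, polyene)
  purrr::list_rbind(purrr::map(geoms, ring_dihedrals))
}

#' Transition-dipole axis of a chromophore
#'
#' The strongly allowed S0→S2 transition of a carotenoid is polarized along
#' the polyene chain. The dipole is placed at the centroid of the polyene
#' atoms, directed along their principal axis (largest-variance direction),
#' with the sign fixed so the first non-zero component is positive.
#'
#' @param geom A [chromophore_geometry()].
#' @param magnitude Transition-dipole magnitude in Debye. Default 13 D, a
#'   typical carotenoid S0→S2 value.
#' @return A `transition_dipole`: list with `center` (Å), `direction` (unit
#'   vector) and `magnitude` (D).
#' @export
transition_dipole_axis <- function(geom, magnitude = 13) {
  stopifnot(inherits(geom, "chromophore_geometry"), magnitude >= 0)
  xyz <- geom$coords[geom$polyene, , drop = FALSE]
  center <- colMeans(xyz)
  centered <- sweep(xyz, 2, center)
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  if (ev$values[1] < 1e-12 ||
      (ev$values[1] - ev$values[2]) / ev$values[1] < 1e-6) {
    rlang::abort("degenerate principal axes: polyene has no unique long axis.",
                 class = "carospec_degenerate_axis")
  }
  direction <- ev$vectors[, 1]
  nz <- which(abs(direction) > 1e-12)[1]
  if (direction[nz] < 0) direction <- -direction
  transition_dipole(center, direction, magnitude)
}

#' @rdname transition_dipole_axis
#' @param center Numeric length-3 point (Å).
#' @param direction Numeric length-3 vector; normalized internally.
#' @export
transition_dipole <- function(center, direction, magnitude) {
  nrm <- sqrt(sum(direction^2))
  stopifnot(nrm > 0, magnitude >= 0)
  structure(
    list(center = as.numeric(center),
         direction = as.numeric(direction) / nrm,
         magnitude = magnitude),
    class = "transition_dipole"
  )
}

#' @export
print.transition_dipole <- function(x, ...) {
  cat(sprintf("<transition_dipole> %.2f D at (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
              x$magnitude, x$center[1], x$center[2], x$center[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Separation and orientation factor of a dipole pair
#'
#' Computes the centre–centre distance R and the dimensionless orientation
#' factor \eqn{\kappa = \hat a \cdot \hat b - 3 (\hat a \cdot \hat R)(\hat b
#' \cdot \hat R)} of two transition dipoles. \eqn{\kappa} is bounded in
#' \eqn{[-2, 2]}: +1 for parallel dipoles stacked perpendicular to R (the
#' H-aggregate geometry), −2 for collinear head-to-tail (J-aggregate).
#'
#' @param a,b `transition_dipole` objects.
#' @return One-row tibble: `r_angstrom`, `kappa`.
#' @export
pair_geometry <- function(a, b) {
  stopifnot(inherits(a, "transition_dipole"), inherits(b, "transition_dipole"))
  rv <- b$center - a$center
  r <- sqrt(sum(rv^2))
  if (r < 1e-9) {
    rlang::abort("dipole centers coincide: geometry is singular.",
                 class = "carospec_singular_geometry")
  }
  rhat <- rv / r
  kappa <- sum(a$direction * b$direction) -
    3 * sum(a$direction * rhat) * sum(b$direction * rhat)
  tibble::tibble(r_angstrom = r, kappa = kappa)
}
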