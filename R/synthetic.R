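# Synthetic-data generators: seeded stand-ins for the QM/MD engines that
# would normally produce dihedral ensembles, snapshot absorption maxima and
# chromophore coordinates. All generators are pure functions of their
# arguments plus an explicit seed (withr::with_seed — no global RNG state
# leaks).

#' Sample angles from a von Mises distribution
#'
#' The von Mises distribution is the circular analogue of the Gaussian:
#' correct support (the circle) and wrap-around behaviour for torsion
#' angles. Sampling uses the Best–Fisher (1979) rejection algorithm.
#' `kappa = 0` gives the uniform circular distribution.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction (degrees).
#' @param kappa Concentration parameter, >= 0 (larger = tighter).
#' @return Numeric vector of angles in (−180, 180].
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu_deg))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) {
    return(wrap_deg(mu_deg + stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        theta[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  wrap_deg(mu_deg + theta * 180 / pi)
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  ifelse(y == -180, 180, y)
}

#' Default end-ring dihedral mixture
#'
#' A two-component von Mises mixture emulating the conformational scatter of
#' a protein-bound carotenoid whose beta2 ring stays nominally s-trans
#' (|phi2| > 90°) while beta1 ranges widely: a concentrated s-cis-like
#' component near (45°, 170°) plus a broad component near (120°, 140°)
#' spreading beta1 over most of its range. Illustrative defaults — the
#' component placement mimics the qualitative MD scatter, not fitted values.
#'
#' @return Tibble with columns `mu1_deg`, `mu2_deg`, `kappa`, `weight`.
#' @export
default_dihedral_mixture <- function() {
  tibble::tibble(
    mu1_deg = c(45, 120),
    mu2_deg = c(170, 140),
    kappa = c(8, 3),
    weight = c(0.6, 0.4)
  )
}

#' Sample a snapshot ensemble of end-ring dihedrals
#'
#' Draws each snapshot from a weighted mixture of bivariate (independent
#' phi1, phi2) von Mises components. Identical seeds give bit-identical
#' ensembles.
#'
#' @param components Mixture specification: data frame with `mu1_deg`,
#'   `mu2_deg`, `kappa`, `weight` (weights positive, summing to 1). See
#'   [default_dihedral_mixture()].
#' @param n Number of snapshots.
#' @param seed Integer seed.
#' @return Tibble: `snapshot`, `component`, `phi1_deg`, `phi2_deg`.
#' @export
sample_dihedral_ensemble <- function(components = default_dihedral_mixture(),
                                     n = 51, seed = 1) {
  stopifnot(is.data.frame(components),
            all(c("mu1_deg", "mu2_deg", "kappa", "weight") %in%
                  names(components)),
            n >= 1)
  if (any(components$weight <= 0) ||
      abs(sum(components$weight) - 1) > 1e-8) {
    rlang::abort("mixture weights must be positive and sum to 1.",
                 class = "carospec_input_error")
  }
  if (any(components$kappa < 0)) {
    rlang::abort("von Mises concentrations must be >= 0.",
                 class = "carospec_input_error")
  }
  withr::with_seed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE,
                       prob = components$weight)
    phi1 <- numeric(n)
    phi2 <- numeric(n)
    for (k in seq_len(nrow(components))) {
      idx <- which(comp == k)
      if (length(idx)) {
        phi1[idx] <- rvonmises_deg(length(idx), components$mu1_deg[k],
                                   components$kappa[k])
        phi2[idx] <- rvonmises_deg(length(idx), components$mu2_deg[k],
                                   components$kappa[k])
      }
    }
    tibble::tibble(snapshot = seq_len(n), component = comp,
                   phi1_deg = phi1, phi2_deg = phi2)
  })
}

#' Simulate a snapshot set of absorption maxima
#'
#' I.i.d. Gaussian draws — the minimal generative model consistent with a
#' reported ensemble mean and standard deviation.
#'
#' @param mean_nm,sd_nm Ensemble mean and SD (nm); `sd_nm >= 0`.
#' @param n Number of snapshots.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_snapshot_lambdas <- function(mean_nm, sd_nm, n, seed = 1) {
  stopifnot(sd_nm >= 0, n >= 1, mean_nm > 0)
  withr::with_seed(seed, stats::rnorm(n, mean_nm, sd_nm))
}

# NeRF atom placement: position d with |cd| = bond, angle(b,c,d) = angle_deg
# and dihedral(a,b,c,d) = torsion_deg (IUPAC sign).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  phi <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

euler_rotation <- function(alpha_deg, beta_deg, gamma_deg) {
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  g <- gamma_deg * pi / 180
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3)
  rz %*% ry %*% rx
}

#' Build an idealized carotenoid chromophore
#'
#' Constructs a planar all-trans polyene chain (ideal 120° sp2 angles,
#' alternating 1.35/1.45 Å double/single bonds — conventional values) with a
#' two-atom ring stub at each end set to the requested ring–chain torsions.
#' Atom names are compatible with [default_quadruples()]; the polyene
#' centroid sits at the origin with the chain along x.
#'
#' @param chain_id Chain identifier.
#' @param n_chain Number of polyene chain atoms (>= 8).
#' @param torsions Length-2 numeric: the beta1 and beta2 ring torsions
#'   (degrees).
#' @return A [chromophore_geometry()].
#' @export
build_toy_chromophore <- function(chain_id = "A", n_chain = 10,
                                  torsions = c(45, 170)) {
  if (n_chain < 8) {
    rlang::abort("`n_chain` must be >= 8.", class = "carospec_input_error")
  }
  if (length(torsions) != 2 || any(!is.finite(torsions))) {
    rlang::abort("`torsions` must be two finite angles (degrees).",
                 class = "carospec_input_error")
  }
  bonds <- rep(c(1.35, 1.45), length.out = n_chain - 1)
  pos <- matrix(0, n_chain, 3)
  dir_angle <- rep(c(30, -30), length.out = n_chain - 1) * pi / 180
  for (i in 2:n_chain) {
    step <- bonds[i - 1] * c(cos(dir_angle[i - 1]), sin(dir_angle[i - 1]), 0)
    pos[i, ] <- pos[i - 1, ] + step
  }
  chain_names <- c("C7", "C8", paste0("C", 8 + seq_len(n_chain - 4)),
                   "C8'", "C7'")
  c6 <- place_atom(pos[3, ], pos[2, ], pos[1, ], 1.46, 120, 180)
  c5 <- place_atom(pos[2, ], pos[1, ], c6, 1.40, 120, torsions[1])
  c6p <- place_atom(pos[n_chain - 2, ], pos[n_chain - 1, ], pos[n_chain, ],
                    1.46, 120, 180)
  c5p <- place_atom(pos[n_chain - 1, ], pos[n_chain, ], c6p, 1.40, 120,
                    torsions[2])
  coords <- rbind(c5, c6, pos, c6p, c5p)
  rownames(coords) <- c("C5", "C6", chain_names, "C6'", "C5'")
  coords <- sweep(coords, 2, colMeans(pos))  # polyene centroid at origin
  chromophore_geometry(chain_id, "CAN", coords, polyene = chain_names)
}

#' Build an idealized stacked carotenoid dimer
#'
#' Two identical toy chromophores: monomer A centred at the origin with its
#' chain along x, monomer B rotated by the given Euler angles (z-y-x
#' convention, degrees) and displaced by `r_sep` along z — the head-to-head
#' stacked geometry of a crystallographic carotenoid dimer (~5 Å ring–ring
#' separation). With zero rotation the transition dipoles are parallel and
#' perpendicular to the separation vector (orientation factor +1, the
#' H-aggregate limit).
#'
#' @param r_sep Centre–centre separation (Å), > 0.
#' @param orientation Length-3 Euler angles (degrees) applied to monomer B.
#' @param n_chain Polyene chain atoms per monomer (>= 8).
#' @param torsions Length-2 ring torsions (degrees), shared by both
#'   monomers.
#' @return List of two [chromophore_geometry()] objects (chains A and B).
#' @export
build_toy_dimer <- function(r_sep = 5, orientation = c(0, 0, 0),
                            n_chain = 10, torsions = c(45, 170)) {
  if (r_sep <= 0) {
    rlang::abort("`r_sep` must be positive.", class = "carospec_input_error")
  }
  if (length(orientation) != 3 || any(!is.finite(orientation))) {
    rlang::abort("`orientation` must be three finite Euler angles (degrees).",
                 class = "carospec_input_error")
  }
  a <- build_toy_chromophore("A", n_chain, torsions)
  rot <- euler_rotation(orientation[1], orientation[2], orientation[3])
  coords_b <- a$coords %*% t(rot)
  coords_b <- sweep(coords_b, 2, c(0, 0, r_sep), `+`)
  rownames(coords_b) <- rownames(a$coords)
  b <- chromophore_geometry("B", "CAN", coords_b, polyene = a$polyene)
  list(a, b)
}

#' Write chromophore geometries as a PDB fixture
#'
#' Emits standard fixed-column HETATM records (residue name from each
#' geometry, one residue per chain, occupancy 1.00). Round-trips through
#' [read_chromophores()] to 1e-3 Å — the PDB coordinate precision.
#'
#' @param geoms List of [chromophore_geometry()] objects (may be empty: a
#'   valid header-only file is written, which reads back as residue-not-found).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(geoms, path) {
  stopifnot(is.list(geoms),
            all(purrr::map_lgl(geoms, inherits, "chromophore_geometry")))
  lines <- c("REMARK   6 SYNTHETIC CHROMOPHORE FIXTURE")
  serial <- 0L
  for (g in geoms) {
    coords <- g$coords
    if (any(coords > 9999.999 | coords < -999.999)) {
      rlang::abort("coordinates exceed the fixed-column PDB range.",
                   class = "carospec_format_overflow")
    }
    for (i in seq_len(nrow(coords))) {
      serial <- serial + 1L
      name <- rownames(coords)[i]
      padded <- if (nchar(name) <= 3) sprintf(" %-3s", name)
                else sprintf("%-4s", name)
      lines <- c(lines, sprintf(
        "HETATM%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, padded, g$resid, g$chain, 1L,
        coords[i, 1], coords[i, 2], coords[i, 3], 1, 0,
        substr(name, 1, 1)
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
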