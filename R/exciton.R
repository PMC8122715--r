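# Point-dipole prefactor: V[cm^-1] = KAPPA_CM1 * kappa * mu_a mu_b / R^3
# with mu in Debye and R in Angstrom; 5034 cm^-1 A^3 / D^2 from SI constants
# (mu^2 / (4 pi eps0 R^3) expressed in wavenumbers, 4 s.f.).
DIPOLE_COUPLING_CM1 <- 5034

#' Assemble a Frenkel exciton system
#'
#' A Frenkel exciton Hamiltonian has the localized excitation (site) energies
#' of the chromophores on its diagonal and the inter-chromophore electronic
#' energy-transfer (EET) couplings off-diagonal. Its eigenstates are the
#' delocalized absorbing states of the assembly.
#'
#' @param site_energies_ev Numeric vector of site energies (eV), length N >= 1.
#' @param couplings Either a full symmetric N x N matrix (eV, zero diagonal)
#'   or a data frame with columns `i`, `j`, `v_ev` listing couplings by
#'   1-based site index (each unordered pair at most once; no self-coupling).
#'   `NULL` means no coupling.
#' @param dipoles Optional list of [transition_dipole()] objects, one per
#'   site; required for intensity calculations in [exciton_spectrum()].
#' @return An `exciton_system` object.
#' @examples
#' sys <- exciton_system(c(2.551, 2.427),
#'                       tibble::tibble(i = 1, j = 2, v_ev = 0.061))
#' diagonalize(sys)
#' @export
exciton_system <- function(site_energies_ev, couplings = NULL, dipoles = NULL) {
  stopifnot(is.numeric(site_energies_ev), length(site_energies_ev) >= 1,
            all(is.finite(site_energies_ev)))
  n <- length(site_energies_ev)
  v <- matrix(0, n, n)
  if (is.matrix(couplings)) {
    stopifnot(all(dim(couplings) == c(n, n)), all(is.finite(couplings)))
    if (max(abs(couplings - t(couplings))) > 1e-12) {
      rlang::abort("coupling matrix is not symmetric.",
                   class = "carospec_input_error")
    }
    if (any(abs(diag(couplings)) > 0)) {
      rlang::abort("coupling matrix must have a zero diagonal.",
                   class = "carospec_input_error")
    }
    v <- (couplings + t(couplings)) / 2
    diag(v) <- 0
  } else if (!is.null(couplings)) {
    stopifnot(is.data.frame(couplings),
              all(c("i", "j", "v_ev") %in% names(couplings)))
    if (nrow(couplings) > 0) {
      if (any(couplings$i < 1 | couplings$i > n | couplings$j < 1 |
                couplings$j > n)) {
        rlang::abort("coupling site indices out of range.",
                     class = "carospec_input_error")
      }
      if (any(couplings$i == couplings$j)) {
        rlang::abort("self-coupling (i == j) is not allowed.",
                     class = "carospec_input_error")
      }
      key <- paste(pmin(couplings$i, couplings$j),
                   pmax(couplings$i, couplings$j))
      if (anyDuplicated(key)) {
        rlang::abort("duplicate coupling entries for the same site pair.",
                     class = "carospec_input_error")
      }
      if (any(!is.finite(couplings$v_ev))) {
        rlang::abort("couplings must be finite.",
                     class = "carospec_input_error")
      }
      for (k in seq_len(nrow(couplings))) {
        v[couplings$i[k], couplings$j[k]] <- couplings$v_ev[k]
        v[couplings$j[k], couplings$i[k]] <- couplings$v_ev[k]
      }
    }
  }
  if (!is.null(dipoles)) {
    stopifnot(length(dipoles) == n,
              all(purrr::map_lgl(dipoles, inherits, "transition_dipole")))
  }
  structure(
    list(site_energies_ev = as.numeric(site_energies_ev),
         coupling_ev = v, dipoles = dipoles),
    class = "exciton_system"
  )
}

#' @export
print.exciton_system <- function(x, ...) {
  n <- length(x$site_energies_ev)
  cat("<exciton_system> ", n, " site(s)\n", sep = "")
  cat("  site energies (eV): ", paste(signif(x$site_energies_ev, 5),
                                      collapse = ", "), "\n", sep = "")
  if (n > 1) {
    cat("  max |coupling|: ", signif(max(abs(x$coupling_ev)), 4), " eV\n",
        sep = "")
  }
  invisible(x)
}

#' Point-dipole excitonic coupling between two transition dipoles
#'
#' The dipole–dipole approximation to the EET coupling:
#' \deqn{V = 5034 \, \kappa \, \mu_a \mu_b / R^3 \ \mathrm{cm^{-1}}}
#' with dipole magnitudes in Debye, centre separation R in Å and \eqn{\kappa}
#' the orientation factor from [pair_geometry()]. The result is returned in
#' eV. Below R = 1 Å the point-dipole picture has no validity and the result
#' carries a `near_singular` attribute set to `TRUE`.
#'
#' @param a,b `transition_dipole` objects.
#' @return Coupling in eV (scalar), with attribute `near_singular`.
#' @export
point_dipole_coupling <- function(a, b) {
  geo <- pair_geometry(a, b)
  v_cm1 <- DIPOLE_COUPLING_CM1 * geo$kappa * a$magnitude * b$magnitude /
    geo$r_angstrom^3
  out <- wavenumber_to_ev(v_cm1)
  attr(out, "near_singular") <- geo$r_angstrom < 1
  out
}

#' Diagonalize a Frenkel exciton system
#'
#' Symmetric eigendecomposition of the exciton Hamiltonian. Eigenvalues are
#' sorted in descending energy (the shorter-wavelength state first) and each
#' eigenvector's sign is fixed so its largest-magnitude coefficient is
#' positive. For two sites the eigenvalues obey the closed form
#' \eqn{\bar E \pm \sqrt{\Delta^2 + V^2}} with \eqn{\Delta} the half-gap.
#'
#' @param system An [exciton_system()].
#' @return An `exciton_result`: `energies_ev` (descending), `wavelengths_nm`,
#'   `vectors` (orthonormal columns, one per state), `intensities` (relative
#'   oscillator strengths, present when the system carries site dipoles), and
#'   the system itself. [generics::tidy()] gives the per-state table.
#' @export
diagonalize <- function(system) {
  stopifnot(inherits(system, "exciton_system"))
  h <- system$coupling_ev
  diag(h) <- system$site_energies_ev
  eig <- eigen(h, symmetric = TRUE)  # eigen() returns decreasing values
  vec <- eig$vectors
  for (k in seq_len(ncol(vec))) {
    lead <- which.max(abs(vec[, k]))
    if (vec[lead, k] < 0) vec[, k] <- -vec[, k]
  }
  intensities <- NULL
  if (!is.null(system$dipoles)) {
    mu <- t(vapply(system$dipoles,
                   function(d) d$magnitude * d$direction, numeric(3)))
    state_mu <- crossprod(vec, mu)           # N states x 3
    intensities <- rowSums(state_mu^2)
  }
  structure(
    list(energies_ev = eig$values,
         wavelengths_nm = ev_to_nm(eig$values),
         vectors = vec,
         intensities = intensities,
         system = system),
    class = "exciton_result"
  )
}

#' @export
print.exciton_result <- function(x, ...) {
  cat("<exciton_result> ", length(x$energies_ev), " state(s)\n", sep = "")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' @rdname diagonalize
#' @param x An `exciton_result`.
#' @param ... Unused.
#' @export
tidy.exciton_result <- function(x, ...) {
  out <- tibble::tibble(
    state = seq_along(x$energies_ev),
    energy_ev = x$energies_ev,
    wavelength_nm = x$wavelengths_nm
  )
  if (!is.null(x$intensities)) out$intensity <- x$intensities
  out
}

#' @rdname diagonalize
#' @export
glance.exciton_result <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$energies_ev),
    trace_ev = sum(x$energies_ev),
    splitting_ev = max(x$energies_ev) - min(x$energies_ev)
  )
}

#' Excitonic absorption spectrum
#'
#' Builds the stick spectrum of an exciton result — state k carries intensity
#' \eqn{|\sum_i c_{ki} \mu_i \hat d_i|^2}, the squared transition dipole of
#' the delocalized state — and broadens it with a Gaussian lineshape. The
#' total intensity satisfies the dipole-strength sum rule
#' \eqn{\sum_k I_k = \sum_i \mu_i^2}, independent of the couplings.
#'
#' @param result An `exciton_result` computed from a system with site
#'   dipoles.
#' @param fwhm Gaussian full width at half maximum (nm).
#' @inheritParams broaden_spectrum
#' @return A `caro_spectrum` tibble; the stick table is attached as the
#'   `sticks` attribute.
#' @export
exciton_spectrum <- function(result, fwhm,
                             grid_from = 350, grid_to = 650, grid_step = 0.1) {
  stopifnot(inherits(result, "exciton_result"))
  if (is.null(result$intensities)) {
    rlang::abort("system has no site dipoles: intensities are unavailable.",
                 class = "carospec_config_error")
  }
  sticks <- tibble::tibble(
    wavelength_nm = result$wavelengths_nm,
    intensity = result$intensities
  )
  sp <- broaden_spectrum(sticks, fwhm, grid_from, grid_to, grid_step)
  attr(sp, "sticks") <- sticks
  sp
}

#' Read and write exciton systems as JSON
#'
#' Format: `site_energies_ev` (array), `couplings` (array of `[i, j, v_ev]`
#' triples, 1-based), optional `dipoles` (array of objects with `center`,
#' `direction`, `magnitude_debye`).
#'
#' @param system An `exciton_system`.
#' @param path File path.
#' @return Reader returns an `exciton_system`; writer returns `path`
#'   invisibly.
#' @export
write_exciton_json <- function(system, path) {
  stopifnot(inherits(system, "exciton_system"))
  n <- length(system$site_energies_ev)
  trips <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && system$coupling_ev[i, j] != 0) {
        trips[[length(trips) + 1]] <- c(i, j, system$coupling_ev[i, j])
      }
    }
  }
  dip <- NULL
  if (!is.null(system$dipoles)) {
    dip <- purrr::map(system$dipoles, function(d) {
      list(center = d$center, direction = d$direction,
           magnitude_debye = d$magnitude)
    })
  }
  jsonlite::write_json(
    list(site_energies_ev = system$site_energies_ev, couplings = trips,
         dipoles = dip),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_exciton_json
#' @export
read_exciton_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  couplings <- NULL
  if (length(x$couplings) > 0) {
    cm <- matrix(unlist(x$couplings), ncol = 3, byrow = !is.matrix(x$couplings))
    if (is.matrix(x$couplings)) cm <- x$couplings
    couplings <- tibble::tibble(i = cm[, 1], j = cm[, 2], v_ev = cm[, 3])
  }
  dipoles <- NULL
  if (!is.null(x$dipoles) && length(x$dipoles) > 0) {
    dipoles <- purrr::map(seq_len(nrow(x$dipoles)), function(k) {
      transition_dipole(unlist(x$dipoles$center[k]),
                        unlist(x$dipoles$direction[k]),
                        x$dipoles$magnitude_debye[k])
    })
  }
  exciton_system(x$site_energies_ev, couplings, dipoles)
}
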