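# Reference inputs for the HCP2 / canthaxanthin worked example: QM/MM-derived
# calibration values for the crystal-structure dimer (PDB 6MCJ) and its
# monomers. These numbers are inputs to the pipeline, not results it claims.

#' Calibration anchors for canthaxanthin in HCP2
#'
#' QM/MM-derived absorption maxima of canthaxanthin at known end-ring
#' torsions in three environments: the two crystal-structure monomers
#' (protein), and the carotenoid in n-hexane and in water. These four
#' anchors calibrate the conjugation surface ([calibrate_surface()]).
#'
#' @return Tibble: `model`, `phi1_deg`, `phi2_deg`, `environment`,
#'   `lambda_max_nm`.
#' @export
hcp2_anchors <- function() {
  tibble::tibble(
    model = c("monomer A", "monomer B", "hexane", "water"),
    phi1_deg = c(74.0, 37.2, 40.7, 41.4),
    phi2_deg = c(179.3, 178.3, 143.3, 140.3),
    environment = c("protein", "protein", "hexane", "water"),
    lambda_max_nm = c(478, 492, 465, 470)
  )
}

#' Exciton system of the HCP2 carotenoid dimer
#'
#' The two-site Frenkel system of the crystal-structure dimer: site energies
#' 2.551 eV (486 nm, monomer A) and 2.427 eV (511 nm, monomer B) with an EET
#' coupling of 0.061 eV. Diagonalizing places the upper exciton state at
#' 481 nm.
#'
#' @param dipoles Optional list of two [transition_dipole()] objects to
#'   attach for intensity calculations.
#' @return An [exciton_system()].
#' @export
hcp2_exciton_system <- function(dipoles = NULL) {
  exciton_system(
    site_energies_ev = c(2.551, 2.427),
    couplings = tibble::tibble(i = 1, j = 2, v_ev = 0.061),
    dipoles = dipoles
  )
}

#' Snapshot-ensemble moments for the HCP2 monomers
#'
#' Reported per-monomer mean and sample SD of the absorption maximum over 51
#' evenly spaced molecular-dynamics snapshots; the generative parameters for
#' [simulate_snapshot_lambdas()] and the inputs to [summarize_ensemble()].
#'
#' @return Tibble: `model`, `mean_nm`, `sd_nm`, `n`.
#' @export
hcp2_snapshot_moments <- function() {
  tibble::tibble(
    model = c("monomer A", "monomer B"),
    mean_nm = c(481.9, 477.0),
    sd_nm = c(12.7, 16.1),
    n = c(51L, 51L)
  )
}
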