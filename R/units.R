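# Photophysical unit conversions. Fixed constants:
#   hc = 1239.84198 eV nm, 1 eV = 8065.544 cm^-1 (CODATA e, h, c).
HC_EV_NM <- 1239.84198
WAVENUMBER_PER_EV <- 8065.544

#' Convert wavelength to photon energy
#'
#' Converts a wavelength in nanometres to the corresponding photon energy in
#' electronvolts via \eqn{E = hc/\lambda} with \eqn{hc = 1239.84198} eV nm.
#'
#' @param lambda_nm Numeric vector of wavelengths (nm); must be positive.
#' @return Numeric vector of energies (eV).
#' @examples
#' nm_to_ev(486) # 2.551 eV, the S0 -> S2 site energy of a 486 nm absorber
#' @seealso [ev_to_nm()], [ev_to_wavenumber()]
#' @export
nm_to_ev <- function(lambda_nm) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    rlang::abort("`lambda_nm` must be finite and positive.", class = "carospec_domain_error")
  }
  HC_EV_NM / lambda_nm
}

#' Convert photon energy to wavelength
#'
#' @param energy_ev Numeric vector of photon energies (eV); must be positive.
#' @return Numeric vector of wavelengths (nm).
#' @examples
#' ev_to_nm(2.427) # ~511 nm
#' @export
ev_to_nm <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    rlang::abort("`energy_ev` must be finite and positive.", class = "carospec_domain_error")
  }
  HC_EV_NM / energy_ev
}

#' Convert energy between electronvolts and wavenumbers
#'
#' Signed energies are allowed: couplings and detunings may be negative.
#' Uses 1 eV = 8065.544 cm\eqn{^{-1}}.
#'
#' @param energy_ev,wavenumber_cm1 Numeric vectors (eV, cm\eqn{^{-1}}).
#' @return Numeric vector in the target unit.
#' @examples
#' ev_to_wavenumber(0.061) # ~492 cm^-1, a strong carotenoid-carotenoid coupling
#' @export
ev_to_wavenumber <- function(energy_ev) {
  stopifnot(is.numeric(energy_ev), all(is.finite(energy_ev)))
  energy_ev * WAVENUMBER_PER_EV
}

#' @rdname ev_to_wavenumber
#' @export
wavenumber_to_ev <- function(wavenumber_cm1) {
  stopifnot(is.numeric(wavenumber_cm1), all(is.finite(wavenumber_cm1)))
  wavenumber_cm1 / WAVENUMBER_PER_EV
}
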