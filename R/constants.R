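#' Physical constants used throughout the package
#'
#' CODATA values in SI units, plus the Debye. All internal computations are
#' carried out in SI (seconds, metres, V/m, C·m); user-facing interfaces use
#' the field's customary units (fs, cm\eqn{^{-1}}, Debye, mg/ml, µm).
#'
#' @format A named list with elements `c` (speed of light, m/s), `eps0`
#'   (vacuum permittivity, F/m), `hbar` (reduced Planck constant, J·s),
#'   `NA_` (Avogadro constant, 1/mol) and `debye` (1 Debye in C·m).
#' @export
cet_constants <- list(
  c     = 2.99792458e8,
  eps0  = 8.8541878128e-12,
  hbar  = 1.054571817e-34,
  NA_   = 6.02214076e23,
  debye = 3.33564e-30
)

#' Unit conversions between spectroscopic and SI quantities
#'
#' The linewidth convention is pinned package-wide: a Lorentzian line of
#' full width at half maximum \eqn{\tilde\nu_{FWHM}} (cm\eqn{^{-1}})
#' corresponds to an amplitude dephasing rate \eqn{\Gamma = \pi c\,
#' \tilde\nu_{FWHM}} (rad/s), i.e. the coherence decays as
#' \eqn{e^{-\Gamma t}} and its energy as \eqn{e^{-2\Gamma t}}. A width of
#' 19.4 cm\eqn{^{-1}} therefore corresponds to \eqn{\Gamma^{-1} \approx}
#' 547 fs.
#'
#' @param nu_cm wavenumber(s) in cm\eqn{^{-1}}
#' @param omega angular frequency in rad/s
#' @param fwhm_cm Lorentzian FWHM in cm\eqn{^{-1}}
#' @param gamma amplitude dephasing rate in rad/s (1/s)
#' @param mu_debye transition dipole in Debye
#' @return the converted quantity (rad/s, cm\eqn{^{-1}}, s, or C·m)
#' @examples
#' dephasing_time_fs(19.4)  # ~547 fs
#' @name units
NULL

#' @rdname units
#' @export
wavenumber_to_omega <- function(nu_cm) 2 * pi * cet_constants$c * nu_cm * 100

#' @rdname units
#' @export
omega_to_wavenumber <- function(omega) omega / (2 * pi * cet_constants$c * 100)

#' @rdname units
#' @export
fwhm_to_gamma <- function(fwhm_cm) pi * cet_constants$c * fwhm_cm * 100

#' @rdname units
#' @export
gamma_to_fwhm <- function(gamma) gamma / (pi * cet_constants$c * 100)

#' @rdname units
#' @export
dephasing_time_fs <- function(fwhm_cm) 1e15 / fwhm_to_gamma(fwhm_cm)

#' @rdname units
#' @export
debye_to_Cm <- function(mu_debye) mu_debye * cet_constants$debye

# internal: stop() with a classed condition so callers can test error types
.cet_stop <- function(msg, class) {
  stop(structure(class = c(class, "cetscope_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
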