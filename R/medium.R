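#' Lorentz-oscillator vibrational mode
#'
#' One homogeneously broadened vibrational resonance, parametrized by its
#' center wavenumber, transition dipole moment and Lorentzian FWHM. The
#' FWHM in cm\eqn{^{-1}} equals \eqn{\Gamma/(\pi c)} with \eqn{\Gamma} the
#' amplitude dephasing rate (see [fwhm_to_gamma()]).
#'
#' @param nu_cm center wavenumber (cm\eqn{^{-1}}, > 0)
#' @param mu_debye transition dipole moment \eqn{\mu_{01}} (Debye, ≥ 0)
#' @param fwhm_cm Lorentzian FWHM (cm\eqn{^{-1}}, > 0)
#' @return an object of class `vib_mode`
#' @export
vib_mode <- function(nu_cm, mu_debye, fwhm_cm = 19.4) {
  stopifnot(nu_cm > 0, mu_debye >= 0, fwhm_cm > 0)
  structure(list(nu_cm = nu_cm, mu_debye = mu_debye, fwhm_cm = fwhm_cm),
            class = "vib_mode")
}

#' Bulk sample specification
#'
#' A dilute molecular solution in a thin cuvette: a set of Lorentz modes
#' plus mass concentration, molar mass and path length. The number density
#' entering the susceptibility is \eqn{N = \beta N_A / M}.
#'
#' @param modes list of [vib_mode()]s
#' @param beta_mg_ml mass concentration (mg/ml ≡ kg/m³, ≥ 0)
#' @param molar_mass molar mass M (g/mol, > 0); defaults to
#'   methylsulfonylmethane (DMSO2), 94.13 g/mol
#' @param length_um cuvette path length (µm, ≥ 0)
#' @return an object of class `sample_spec`
#' @export
sample_spec <- function(modes, beta_mg_ml = 10, molar_mass = 94.13,
                        length_um = 30) {
  if (inherits(modes, "vib_mode")) modes <- list(modes)
  stopifnot(all(vapply(modes, inherits, TRUE, "vib_mode")),
            beta_mg_ml >= 0, molar_mass > 0, length_um >= 0)
  structure(list(modes = modes, beta_mg_ml = beta_mg_ml,
                 molar_mass = molar_mass, length_um = length_um),
            class = "sample_spec")
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf("<sample_spec> %d mode(s), %g mg/ml, M = %g g/mol, L = %g um\n",
              length(x$modes), x$beta_mg_ml, x$molar_mass, x$length_um))
  for (m in x$modes)
    cat(sprintf("  %7.1f cm-1  mu = %.2f D  fwhm = %.1f cm-1\n",
                m$nu_cm, m$mu_debye, m$fwhm_cm))
  invisible(x)
}

# number density in 1/m^3 (beta in kg/m^3, molar mass in g/mol)
.number_density <- function(sample)
  sample$beta_mg_ml * cet_constants$NA_ / (sample$molar_mass * 1e-3)

#' Named mode-table presets
#'
#' The four parameter sets for the symmetric/asymmetric SO2 stretching
#' vibrations of solvated DMSO2: experimentally fitted values and three
#' levels of quantum-chemical solvent treatment. Both modes carry the
#' typical homogeneous linewidth of 19.4 cm\eqn{^{-1}} (the per-mode
#' values are not published).
#'
#' @param name one of `"table1_experiment"`, `"table1_explicit_solvation"`,
#'   `"table1_pcm"`, `"table1_no_environment"`
#' @param beta_mg_ml,length_um bulk parameters passed to [sample_spec()]
#' @return a [sample_spec()]
#' @export
sample_preset <- function(name, beta_mg_ml = 10, length_um = 30) {
  tab <- list(
    table1_experiment         = list(c(1135, 0.30), c(1280, 0.38)),
    table1_explicit_solvation = list(c(1148, 0.33), c(1301, 0.41)),
    table1_pcm                = list(c(1142, 0.32), c(1288, 0.37)),
    table1_no_environment     = list(c(1192, 0.24), c(1311, 0.26))
  )
  if (!name %in% names(tab))
    .cet_stop(sprintf("unknown preset '%s'", name), "cet_spec_error")
  modes <- lapply(tab[[name]], function(p) vib_mode(p[1], p[2], 19.4))
  sample_spec(modes, beta_mg_ml = beta_mg_ml, length_um = length_um)
}

#' Read a mode table from CSV
#'
#' Expects columns `nu_cm1, mu_debye, fwhm_cm1` (additional columns are
#' ignored), one row per vibrational mode.
#'
#' @param path CSV file path
#' @inheritParams sample_preset
#' @return a [sample_spec()]
#' @export
read_mode_table <- function(path, beta_mg_ml = 10, length_um = 30) {
  df <- utils::read.csv(path)
  need <- c("nu_cm1", "mu_debye", "fwhm_cm1")
  if (!all(need %in% names(df)))
    .cet_stop("mode table must have columns nu_cm1, mu_debye, fwhm_cm1",
              "cet_io_error")
  modes <- lapply(seq_len(nrow(df)), function(i)
    vib_mode(df$nu_cm1[i], df$mu_debye[i], df$fwhm_cm1[i]))
  sample_spec(modes, beta_mg_ml = beta_mg_ml, length_um = length_um)
}

#' Multi-mode Lorentz susceptibility
#'
#' Evaluates the first-order susceptibility of the molecular solution,
#' \deqn{\chi^{(1)}(\omega) = \sum_k \frac{2}{3}\frac{\beta}{m \hbar
#' \varepsilon_0}\, \frac{\mu_{0k}^2\, \omega_k}{\omega_k^2 - (\omega - i
#' \Gamma_k)^2},}
#' with \eqn{\beta/m = \beta N_A/M} the number density. Under the package
#' Fourier convention (forward kernel \eqn{e^{-i\omega t}}) this pole
#' choice gives \eqn{\mathrm{Im}\,\chi < 0} at resonance for positive
#' frequencies, which is the absorbing sign; on a symmetric axis
#' \eqn{\chi(-\omega) = \chi(\omega)^*} so that propagated fields stay
#' real.
#'
#' @param sample a [sample_spec()]
#' @param omega signed angular-frequency axis (rad/s)
#' @return an object of class `susceptibility_spectrum` with fields
#'   `omega` and complex `chi`
#' @export
susceptibility <- function(sample, omega) {
  stopifnot(inherits(sample, "sample_spec"), all(is.finite(omega)))
  N <- .number_density(sample)
  chi <- rep(0 + 0i, length(omega))
  for (m in sample$modes) {
    wk <- wavenumber_to_omega(m$nu_cm)
    gk <- fwhm_to_gamma(m$fwhm_cm)
    mu <- debye_to_Cm(m$mu_debye)
    chi <- chi + (2 / 3) * (N / (cet_constants$hbar * cet_constants$eps0)) *
      mu^2 * wk / (wk^2 - (omega - 1i * gk)^2)
  }
  structure(list(omega = omega, chi = chi), class = "susceptibility_spectrum")
}

# per-mode susceptibility (used by the polarization dual-route check)
.susceptibility_one <- function(sample, mode_idx, omega) {
  s1 <- sample
  s1$modes <- sample$modes[mode_idx]
  susceptibility(s1, omega)
}

#' Linear propagation factor of the cuvette
#'
#' \eqn{H(\omega) = \exp[-i (n(\omega) - 1)\,\omega L / c]} with
#' \eqn{n = \sqrt{1 + \chi}} (branch with \eqn{\mathrm{Re}\, n > 0}). The
#' solvent background is folded into the reference waveform, so `H`
#' encodes the solute response only. `thin = TRUE` selects the first-order
#' (single-scattering) factor \eqn{1 - i \chi \omega L/(2 c)} used by the
#' closed-form oracles.
#'
#' @param chi a `susceptibility_spectrum`
#' @param length_um path length (µm)
#' @param thin use the thin-sample expansion instead of the exact
#'   exponential
#' @return complex vector `H` on `chi$omega`
#' @export
transfer_function <- function(chi, length_um, thin = FALSE) {
  stopifnot(inherits(chi, "susceptibility_spectrum"))
  L <- length_um * 1e-6
  om <- chi$omega
  if (thin)
    return(1 - 1i * chi$chi * om * L / (2 * cet_constants$c))
  if (any(Re(1 + chi$chi) <= 0))
    .cet_stop("Re(1 + chi) <= 0: invalid medium for the sqrt branch",
              "cet_medium_error")
  n <- sqrt(1 + chi$chi)
  exp(-1i * (n - 1) * om * L / cet_constants$c)
}

#' Propagate a waveform through the sample
#'
#' Multiplies the field spectrum by the transfer function of the solute
#' layer and transforms back. The output is real (Hermitian symmetry) and
#' its energy spectral density never exceeds the input's (passive medium).
#' Errors if the free-induction tail has not decayed at the end of the
#' grid (window too short for the narrowest line).
#'
#' @param w a [waveform()]
#' @param sample a [sample_spec()]
#' @param thin propagate with the thin-sample transfer function
#' @return the transmitted [waveform()]
#' @export
propagate <- function(w, sample, thin = FALSE) {
  stopifnot(inherits(w, "waveform"), inherits(sample, "sample_spec"))
  # the grid must hold >= 10 dephasing times after the (t = 0 centred) pulse
  gmin <- min(vapply(sample$modes, function(m) fwhm_to_gamma(m$fwhm_cm), 1.0))
  t_end <- (w$grid$t0_fs + w$grid$dt_fs * (w$grid$n - 1)) * 1e-15
  if (sample$beta_mg_ml > 0 && t_end < 10 / gmin)
    .cet_stop("grid too short for the free-induction decay (< 10/Gamma)",
              "cet_window_error")
  out <- .apply_filter(w$field, w$grid$dt_fs * 1e-15, function(om)
    transfer_function(susceptibility(sample, om), sample$length_um, thin))
  pk <- max(abs(out))
  ntail <- max(2L, round(0.01 * w$grid$n))
  if (pk > 0 && max(abs(utils::tail(out, ntail))) > 1e-4 * pk)
    .cet_stop("transmitted field truncated at the grid end", "cet_window_error")
  meta <- w$meta
  meta$propagated <- TRUE
  waveform(w$grid, out, meta)
}

#' Energy spectral density of a waveform
#'
#' One-sided ESD on a wavenumber axis, normalized so that
#' \eqn{(c\varepsilon_0/\pi)\int \mathrm{ESD}\, d\omega} equals the pulse
#' fluence (Parseval).
#'
#' @param w a [waveform()]
#' @return data frame with columns `nu_cm` and `esd` (|E(w)|², (V/m)²·s²)
#' @export
esd <- function(w) {
  stopifnot(inherits(w, "waveform"))
  dt <- w$grid$dt_fs * 1e-15
  npad <- .pad_length(w$grid$n)
  om <- .fft_omega(npad, dt)
  Ew <- stats::fft(c(w$field, rep(0, npad - w$grid$n))) * dt
  pos <- om > 0
  data.frame(nu_cm = omega_to_wavenumber(om[pos]),
             esd = Mod(Ew[pos])^2)[order(om[pos]), ]
}

#' Absorbance from reference and sample waveforms
#'
#' The amplitude-logarithm absorbance
#' \eqn{A(\tilde\nu) = \log_{10}|E_{ref}(\omega)| -
#' \log_{10}|E_{sam}(\omega)|}, evaluated on a requested wavenumber axis
#' by linear interpolation of the FFT spectra. Bins where the reference
#' ESD falls below `floor` times its maximum are masked (`NA`).
#'
#' @param ref,sam [waveform()]s on the same grid
#' @param nu_cm requested wavenumber axis (cm\eqn{^{-1}})
#' @param floor relative reference-ESD floor for masking
#' @return data frame with columns `nu_cm` and `absorbance`
#' @export
absorbance <- function(ref, sam, nu_cm, floor = 1e-4) {
  stopifnot(inherits(ref, "waveform"), inherits(sam, "waveform"))
  if (!same_grid(ref$grid, sam$grid))
    .cet_stop("reference and sample must share a grid", "cet_grid_error")
  er <- esd(ref)
  es <- esd(sam)
  ar <- stats::approx(er$nu_cm, er$esd, nu_cm, rule = 2)$y
  as_ <- stats::approx(es$nu_cm, es$esd, nu_cm, rule = 2)$y
  mask <- ar < floor^2 * max(er$esd)  # floor applies to |E|, ESD is |E|^2
  A <- 0.5 * (log10(ar) - log10(as_)) # amplitude absorbance from ESD
  A[mask] <- NA_real_
  if (all(mask)) warning("absorbance: no overlap above the reference floor")
  data.frame(nu_cm = nu_cm, absorbance = A)
}
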