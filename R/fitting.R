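#' Fit Lorentz-mode parameters to an absorbance spectrum
#'
#' Nonlinear least squares of the forward-model absorbance (the
#' amplitude-logarithm convention of [absorbance()], i.e.
#' \eqn{-\log_{10}|H(\omega)|} for the given bulk parameters) in the
#' per-mode parameters \eqn{(\tilde\nu_k, \mu_{0k},
#' \mathrm{FWHM}_k)}. Because the forward model carries \eqn{\beta}, M and
#' L, the fitted line strengths come out directly as transition dipole
#' moments in Debye. Initial centers are seeded by peak picking (local
#' maxima above 3× the median absolute deviation, descending height);
#' widths start at 20 cm\eqn{^{-1}}. Levenberg–Marquardt via
#' \pkg{minpack.lm}.
#'
#' @param spectrum data frame with columns `nu_cm` and `absorbance` (as
#'   returned by [absorbance()]; `NA` bins are dropped)
#' @param n_modes number of Lorentzians to fit (≥ 1)
#' @param sample a [sample_spec()] carrying \eqn{\beta}, M, L (its modes
#'   are ignored); fitted modes are interpreted in this bulk context
#' @param init optional list of [vib_mode()]s overriding the automatic
#'   initialization
#' @param intensity_convention fit \eqn{2\times} the amplitude absorbance
#'   (for spectra recorded on the intensity-log convention)
#' @param thin use the thin-sample forward model
#' @return an object of class `fit_result`: fitted `modes`, `covariance`,
#'   RMS `residual`, and the underlying `fit` object
#' @export
fit_lorentzians <- function(spectrum, n_modes, sample, init = NULL,
                            intensity_convention = FALSE, thin = FALSE) {
  stopifnot(n_modes >= 1, inherits(sample, "sample_spec"))
  ok <- is.finite(spectrum$absorbance)
  nu <- spectrum$nu_cm[ok]
  A <- spectrum$absorbance[ok]
  if (!length(nu) || max(abs(A)) == 0)
    .cet_stop("absorbance spectrum has zero amplitude: nothing to fit",
              "cet_fit_error")
  if (is.null(init)) {
    thr <- 3 * stats::mad(A, center = 0)
    loc <- which(A[2:(length(A) - 1)] > A[1:(length(A) - 2)] &
                   A[2:(length(A) - 1)] >= A[3:length(A)]) + 1L
    loc <- loc[A[loc] > thr]
    loc <- loc[order(-A[loc])]
    if (length(loc) < n_modes) {
      warning("fewer prominent peaks than n_modes; padding initial centers")
      extra <- round(seq(1, length(A), length.out = n_modes + 2))[2:(n_modes + 1)]
      loc <- unique(c(loc, extra))[seq_len(n_modes)]
    }
    loc <- sort(loc[seq_len(n_modes)])
    init <- lapply(loc, function(i) {
      # thin-sample peak: A = alpha_peak L / (2 ln 10); invert for mu
      aL <- A[i] * 2 * log(10)
      N <- .number_density(sample)
      L <- sample$length_um * 1e-6
      wk <- wavenumber_to_omega(nu[i])
      gk <- fwhm_to_gamma(20)
      mu2 <- aL * 3 * cet_constants$hbar * cet_constants$eps0 * gk *
        cet_constants$c / (N * wk * L)
      vib_mode(nu[i], max(sqrt(mu2) / cet_constants$debye, 1e-4), 20)
    })
  }
  fac <- if (intensity_convention) 2 else 1
  model_abs <- function(p) {
    modes <- lapply(seq_len(n_modes), function(k)
      vib_mode(p[3 * k - 2], abs(p[3 * k - 1]), abs(p[3 * k])))
    s <- sample
    s$modes <- modes
    H <- transfer_function(susceptibility(s, wavenumber_to_omega(nu)),
                           s$length_um, thin)
    -fac * log10(Mod(H))
  }
  p0 <- unlist(lapply(init, function(m) c(m$nu_cm, m$mu_debye, m$fwhm_cm)))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) model_abs(p) - A,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200))
  p <- fit$par
  modes <- lapply(seq_len(n_modes), function(k)
    vib_mode(p[3 * k - 2], abs(p[3 * k - 1]), abs(p[3 * k])))
  covar <- tryCatch({
    dof <- max(length(A) - length(p), 1)
    sigma2 <- sum(fit$fvec^2) / dof
    sigma2 * solve(fit$hessian / 2)
  }, error = function(e) matrix(NA_real_, length(p), length(p)))
  structure(list(modes = modes, covariance = covar,
                 residual = sqrt(mean(fit$fvec^2)), fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  for (m in x$modes)
    cat(sprintf("  %8.2f cm-1  mu = %.4f D  fwhm = %.2f cm-1\n",
                m$nu_cm, m$mu_debye, m$fwhm_cm))
  cat(sprintf("  RMS residual = %.3g\n", x$residual))
  invisible(x)
}

# in-band spectral energy of a waveform (used by the normalization stage)
.band_energy <- function(w, band_cm) {
  sp <- esd(w)
  sel <- sp$nu_cm >= band_cm[1] & sp$nu_cm <= band_cm[2]
  etot <- pracma::trapz(sp$nu_cm, sp$esd)
  eb <- if (any(sel)) pracma::trapz(sp$nu_cm[sel], sp$esd[sel]) else 0
  if (eb <= 1e-10 * etot)
    .cet_stop("normalization band outside spectral support", "cet_fit_error")
  eb
}

#' Normalize a trace ensemble on a resonance-free spectral band
#'
#' Compensates pulse-energy fluctuations: each trace is rescaled so that
#' the energy it carries in the chosen band (default 984–1051
#' cm\eqn{^{-1}}, where no significant molecular resonances are expected)
#' equals the ensemble-average in-band energy. Returns the averaged trace,
#' pointwise standard errors, and the per-trace scale factors.
#'
#' @param ensemble list of [waveform()]s on a common grid
#' @param band_cm two-element wavenumber interval (cm\eqn{^{-1}})
#' @return list with `mean` ([waveform()]), `se` (pointwise standard
#'   error of the mean field), and `factors`
#' @export
normalize_traces <- function(ensemble, band_cm = c(984, 1051)) {
  stopifnot(length(ensemble) >= 1)
  en <- vapply(ensemble, .band_energy, 1.0, band_cm = band_cm)
  if (any(en <= 0)) .cet_stop("zero in-band energy in a trace",
                              "cet_fit_error")
  target <- mean(en)
  factors <- sqrt(target / en)
  scaled <- mapply(function(w, f) f * w$field, ensemble, factors)
  mean_field <- rowMeans(scaled)
  se <- if (length(ensemble) > 1)
    apply(scaled, 1, stats::sd) / sqrt(length(ensemble)) else
      rep(0, length(mean_field))
  list(mean = waveform(ensemble[[1]]$grid, mean_field,
                       meta = list(n_traces = length(ensemble),
                                   band_cm = band_cm)),
       se = se, factors = factors)
}

#' CET with a Gaussian-propagated error corridor
#'
#' Mirrors the measurement protocol of repeated scan blocks: each repeat
#' supplies an averaged reference and sample trace; the CET of the mean
#' traces is reported together with a pointwise error corridor obtained by
#' first-order Gaussian propagation of the field-trace standard deviations
#' through the CET integral (field errors treated as independent between
#' samples and between the two arms).
#'
#' @param refs,sams lists (≥ 2 repeats) of averaged [waveform()]s
#' @return list with the mean `trace` (a `cet_trace`), the pointwise
#'   corridor half-width `sigma` (J/m²), and the per-repeat CET end
#'   values
#' @export
cet_error_corridor <- function(refs, sams) {
  if (length(refs) < 2 || length(sams) < 2 || length(refs) != length(sams))
    .cet_stop("need >= 2 matched repeats for an error corridor",
              "cet_fit_error")
  grid <- refs[[1]]$grid
  dt <- grid$dt_fs * 1e-15
  Er <- vapply(refs, function(w) w$field, numeric(grid$n))
  Es <- vapply(sams, function(w) w$field, numeric(grid$n))
  mr <- rowMeans(Er)
  ms <- rowMeans(Es)
  sr <- apply(Er, 1, stats::sd) / sqrt(ncol(Er))
  ss <- apply(Es, 1, stats::sd) / sqrt(ncol(Es))
  trace <- cet(waveform(grid, mr), waveform(grid, ms))
  # var of each dI sample: (dI/dE)^2 var(E) for both arms
  ce <- cet_constants$c * cet_constants$eps0
  vI <- (2 * ce)^2 * ((mr * sr)^2 + (ms * ss)^2)
  sigma <- sqrt(cumsum(c(0, (vI[-1] + vI[-length(vI)]) / 4)) * dt^2)
  ends <- vapply(seq_along(refs), function(i) {
    tr <- cet(refs[[i]], sams[[i]])
    tr$cet[length(tr$cet)]
  }, 1.0)
  list(trace = trace, sigma = sigma, repeat_ends = ends)
}
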