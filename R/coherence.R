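#' First-order vibrational coherence driven by a field
#'
#' Evaluates the linear-response coherence of one vibrational mode,
#' \deqn{\rho_{0k}(t) = \frac{i}{\hbar}\,\mu_{0k} \int_0^\infty
#' E(t - t_1)\, e^{-i\omega_k t_1}\, e^{-\Gamma_k t_1}\, dt_1,}
#' by fast convolution of the field with the one-sided oscillator kernel
#' (trapezoid-weighted, truncated where \eqn{e^{-\Gamma t} < 10^{-8}}).
#' The kernel phase follows the package Fourier convention, under which
#' the resonant (co-rotating) half of the real field is the conjugate
#' analytic signal; the magnitude and all observables are
#' convention-independent. With `rwa = TRUE` the field is replaced by its
#' co-rotating half \eqn{\tfrac12 \bar a(t)} (counter-rotating terms —
#' those oscillating at the sum of field and vibrational frequencies —
#' dropped, factor ½ retained so resonant driving is unchanged). With
#' `relax = FALSE` the dephasing \eqn{\Gamma_k} is switched off in the
#' kernel.
#'
#' @param w driving [waveform()]
#' @param mode a [vib_mode()]
#' @param rwa apply the rotating-wave approximation
#' @param relax include dephasing in the kernel
#' @return an object of class `coherence_trajectory` with complex `rho`
#'   (dimensionless) on the waveform's grid
#' @export
coherence_trajectory <- function(w, mode, rwa = FALSE, relax = TRUE) {
  stopifnot(inherits(w, "waveform"), inherits(mode, "vib_mode"))
  wk <- wavenumber_to_omega(mode$nu_cm)
  dt <- w$grid$dt_fs * 1e-15
  if (!rwa && dt > pi / (6 * wk))
    .cet_stop("grid does not resolve 2 w_k (need >= 6 samples per half-cycle)",
              "cet_sampling_error")
  gk <- if (relax) fwhm_to_gamma(mode$fwhm_cm) else 0
  n <- w$grid$n
  nk <- if (gk > 0) min(n, ceiling(log(1e8) / (gk * dt)) + 1L) else n
  t1 <- dt * (seq_len(nk) - 1)
  kern <- exp(-(1i * wk + gk) * t1)
  kern[1] <- kern[1] / 2  # trapezoid end weight at t1 = 0
  drive <- if (rwa) Conj(analytic_signal(w$field)) / 2 else w$field
  npad <- .pad_length(n)
  conv <- stats::fft(stats::fft(c(drive, rep(0, npad - n))) *
                       stats::fft(c(kern, rep(0, npad - nk))),
                     inverse = TRUE) / npad
  rho <- (1i / cet_constants$hbar) * debye_to_Cm(mode$mu_debye) * dt *
    conv[seq_len(n)]
  if (max(Mod(rho)) > 0.1)
    warning("max |rho| > 0.1: first-order perturbation theory is strained")
  structure(list(grid = w$grid, rho = rho, mode = mode, rwa = rwa,
                 relax = relax), class = "coherence_trajectory")
}

#' @export
print.coherence_trajectory <- function(x, ...) {
  cat(sprintf("<coherence_trajectory> %.0f cm-1, rwa = %s, relax = %s, max |rho| = %.3g\n",
              x$mode$nu_cm, x$rwa, x$relax, max(Mod(x$rho))))
  invisible(x)
}

#' Transform a coherence trajectory into the rotating frame
#'
#' Removes the eigenfrequency rotation,
#' \eqn{\tilde\rho(t) = \rho(t)\, e^{+i\omega_k t}}, leaving the slowly
#' varying complex amplitude; under the RWA the result is a smooth curve,
#' without it the counter-rotating term imprints one cycloid bump per
#' field half-cycle. The magnitude is unchanged at every sample.
#'
#' @param traj a `coherence_trajectory`
#' @return a `coherence_trajectory` in the rotating frame
#' @export
rotating_frame <- function(traj) {
  stopifnot(inherits(traj, "coherence_trajectory"))
  wk <- wavenumber_to_omega(traj$mode$nu_cm)
  out <- traj
  out$rho <- traj$rho * exp(1i * wk * grid_times_s(traj$grid))
  out$rotating_frame <- TRUE
  out
}

#' Macroscopic polarization of the sample
#'
#' Either from the time-domain coherences,
#' \eqn{P(t) = \sum_k \tfrac{2}{3} \frac{\beta N_A}{M}\, \mu_{0k}\,
#' \mathrm{Re}\,\rho_{0k}(t)}, or from the frequency domain,
#' \eqn{P(t) = F^{-1}\{\varepsilon_0\, \chi^{(1)}(\omega) E(\omega)\}}.
#' The two routes are the same physical object; with `verify = TRUE` both
#' are computed and an internal-consistency error is raised if they
#' disagree by more than 0.5% RMS.
#'
#' @param w driving [waveform()]
#' @param sample a [sample_spec()]
#' @param mode integer index of a single mode, or `"all"`
#' @param method `"time"` (coherence route) or `"frequency"`
#' @param verify cross-check the two routes
#' @return an object of class `polarization_trace` (`p` in C/m²)
#' @export
polarization <- function(w, sample, mode = "all",
                         method = c("time", "frequency"), verify = FALSE) {
  stopifnot(inherits(w, "waveform"), inherits(sample, "sample_spec"))
  method <- match.arg(method)
  idx <- if (identical(mode, "all")) seq_along(sample$modes) else as.integer(mode)
  p_time <- function() {
    N <- .number_density(sample)
    p <- 0
    for (i in idx) {
      m <- sample$modes[[i]]
      tr <- coherence_trajectory(w, m)
      p <- p + (2 / 3) * N * debye_to_Cm(m$mu_debye) * Re(tr$rho)
    }
    p
  }
  p_freq <- function()
    .apply_filter(w$field, w$grid$dt_fs * 1e-15, function(om)
      cet_constants$eps0 * .susceptibility_one(sample, idx, om)$chi)
  p <- if (method == "time") p_time() else p_freq()
  if (verify) {
    q <- if (method == "time") p_freq() else p_time()
    scale <- sqrt(mean(p^2))
    if (scale > 0 && sqrt(mean((p - q)^2)) / scale > 0.005)
      .cet_stop("time- and frequency-domain polarization routes disagree",
                "cet_consistency_error")
  }
  structure(list(grid = w$grid, p = p, mode = mode, method = method),
            class = "polarization_trace")
}

#' Peak excited-state population of a mode
#'
#' In first order the excited-state population is \eqn{|\rho_{0k}(t)|^2};
#' its maximum gauges the validity of the perturbative treatment.
#'
#' @param traj a `coherence_trajectory`
#' @return max over t of \eqn{|\rho|^2}
#' @export
excited_population <- function(traj) {
  stopifnot(inherits(traj, "coherence_trajectory"))
  max(Mod(traj$rho))^2
}

#' Consistency of CET with the coherence picture
#'
#' In a thin sample the macroscopic CET(t) equals the microscopic energy
#' tally of the coherences: the energy currently stored,
#' \eqn{\sum_k w_k |\rho_k(t)|^2} with \eqn{w_k = \tfrac13 N L\,
#' \hbar\omega_k} per unit area (the orientation-averaged energy per
#' coherence quantum), plus the energy already dissipated,
#' \eqn{\sum_k 2\Gamma_k w_k \int |\rho_k|^2 dt'}. The weight follows
#' from the same orientational average (\eqn{\langle\cos^2\rangle = 1/3})
#' that produces the 2/3 prefactor of the susceptibility, and is
#' validated against the propagation pipeline in the test suite. The
#' relative residual grows with absorbance: the identity is a thin-sample
#' statement.
#'
#' @param cet_trace a `cet_trace` from the propagation pipeline
#' @param trajs list of `coherence_trajectory`s (one per sample mode,
#'   driven by the same reference waveform)
#' @param sample the [sample_spec()] used for the propagation
#' @return list with the reconstructed `model` trace, the relative RMS
#'   `residual` (fraction of the CET maximum), and the regression `scale`
#'   of CET on the model (1 in the thin limit)
#' @export
cet_coherence_check <- function(cet_trace, trajs, sample) {
  stopifnot(inherits(cet_trace, "cet_trace"))
  N <- .number_density(sample)
  L <- sample$length_um * 1e-6
  dt <- cet_trace$grid$dt_fs * 1e-15
  model <- 0
  for (tr in trajs) {
    wk <- wavenumber_to_omega(tr$mode$nu_cm)
    gk <- fwhm_to_gamma(tr$mode$fwhm_cm)
    wgt <- N * L * cet_constants$hbar * wk / 3
    r2 <- Mod(tr$rho)^2
    diss <- c(0, cumsum((r2[-1] + r2[-length(r2)]) / 2 * dt)) * 2 * gk
    model <- model + wgt * (r2 + diss)
  }
  mx <- max(cet_trace$cet)
  if (mx == 0 && max(model) == 0)
    return(list(model = model, residual = 0, scale = NA_real_))
  resid <- sqrt(mean((cet_trace$cet - model)^2)) / mx
  scale <- sum(cet_trace$cet * model) / sum(model^2)
  list(model = model, residual = resid, scale = scale)
}

#' Sub-optical-cycle absorption/emission steps in CET(t)
#'
#' Light-matter energy exchange proceeds in half-cycle strokes: between
#' consecutive zeros of the driving field the transfer has a single sign.
#' This diagnostic locates the field zeros inside the interaction region,
#' classifies each half-cycle increment of CET as compliant when the CET
#' is monotone across it (total variation within 10% of the net change),
#' ignores half-cycles whose increment is below \eqn{10^{-4}} of the CET
#' maximum, and reports the compliant fraction along with the median step
#' period.
#'
#' @param cet_trace a `cet_trace`
#' @param w the reference [waveform()] on the same grid
#' @return list with `fraction_compliant`, `median_step_fs`, `n_steps`
#'   and the zero-crossing times `zeros_fs`
#' @export
subcycle_steps <- function(cet_trace, w) {
  stopifnot(inherits(cet_trace, "cet_trace"), inherits(w, "waveform"))
  if (!same_grid(cet_trace$grid, w$grid))
    .cet_stop("CET trace and waveform grids differ", "cet_grid_error")
  if (max(abs(cet_trace$cet)) == 0)
    return(list(fraction_compliant = NA_real_, median_step_fs = NA_real_,
                n_steps = 0L, zeros_fs = numeric(0)))
  t_fs <- grid_times_fs(w$grid)
  env <- Mod(analytic_signal(w$field))
  active <- env > 0.01 * max(env)
  s <- sign(w$field)
  zc <- which(s[-1] * s[-length(s)] < 0 & active[-1])
  if (length(zc) < 3)
    return(list(fraction_compliant = NA_real_, median_step_fs = NA_real_,
                n_steps = 0L, zeros_fs = numeric(0)))
  # linear interpolation of the zero positions
  zeros_fs <- t_fs[zc] - w$field[zc] * (t_fs[zc + 1] - t_fs[zc]) /
    (w$field[zc + 1] - w$field[zc])
  floor_ <- 1e-4 * max(abs(cet_trace$cet))
  comp <- logical(0)
  for (i in seq_len(length(zc) - 1)) {
    seg <- cet_trace$cet[zc[i]:zc[i + 1]]
    net <- seg[length(seg)] - seg[1]
    if (abs(net) < floor_) next
    tv <- sum(abs(diff(seg)))
    comp <- c(comp, tv <= 1.1 * abs(net))
  }
  list(fraction_compliant = if (length(comp)) mean(comp) else NA_real_,
       median_step_fs = stats::median(diff(zeros_fs)),
       n_steps = length(comp), zeros_fs = zeros_fs)
}

#' Prominent local maxima of a CET trace
#'
#' Utility for counting coherent transients: returns the times of local
#' maxima whose prominence exceeds `prominence` times the trace range,
#' merging maxima closer than `min_sep_fs`.
#'
#' @param cet_trace a `cet_trace`
#' @param prominence minimum prominence as a fraction of the trace range
#' @param min_sep_fs minimum separation between reported maxima (fs)
#' @return data frame with columns `time_fs` and `cet`
#' @export
cet_local_maxima <- function(cet_trace, prominence = 0.02, min_sep_fs = 50) {
  x <- cet_trace$cet
  t_fs <- grid_times_fs(cet_trace$grid)
  n <- length(x)
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(i)) return(data.frame(time_fs = numeric(0), cet = numeric(0)))
  rng <- diff(range(x))
  keep <- vapply(i, function(j) {
    left <- x[seq_len(j - 1)]
    right <- x[seq(j + 1, n)]
    hl <- rev(which(left > x[j]))
    hr <- which(right > x[j])
    vl <- if (length(hl)) min(left[seq(hl[1], j - 1)]) else min(left)
    vr <- if (length(hr)) min(right[seq_len(hr[1])]) else min(right)
    (x[j] - max(vl, vr)) >= prominence * rng
  }, TRUE)
  i <- i[keep]
  # merge clusters closer than min_sep_fs, keeping the highest
  out <- integer(0)
  for (j in i[order(-x[i])]) {
    if (!length(out) || all(abs(t_fs[j] - t_fs[out]) >= min_sep_fs))
      out <- c(out, j)
  }
  out <- sort(out)
  data.frame(time_fs = t_fs[out], cet = x[out])
}
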