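#' Excitation pulse specification
#'
#' Describes a (possibly chirped) Gaussian mid-IR excitation pulse. The
#' duration is the FWHM of the *intensity* envelope (standard ultrafast
#' usage); exactly one of `peak_field` or `fluence` fixes the amplitude.
#'
#' @param center_cm carrier wavenumber (cm\eqn{^{-1}}, > 0)
#' @param fwhm_fs intensity-envelope FWHM duration (fs, > 0)
#' @param peak_field peak field amplitude (V/m); mutually exclusive with
#'   `fluence`
#' @param fluence pulse energy per area (J/m²); mutually exclusive with
#'   `peak_field`
#' @param gdd group-delay dispersion (fs²) applied about `center_cm`
#' @param tod third-order dispersion (fs³)
#' @param cep carrier-envelope phase (rad)
#' @return an object of class `pulse_spec`
#' @export
pulse_spec <- function(center_cm, fwhm_fs, peak_field = NULL, fluence = NULL,
                       gdd = 0, tod = 0, cep = 0) {
  stopifnot(center_cm > 0, fwhm_fs > 0)
  if (is.null(peak_field) == is.null(fluence))
    .cet_stop("exactly one of peak_field or fluence must be given",
              "cet_spec_error")
  structure(list(center_cm = center_cm, fwhm_fs = fwhm_fs,
                 peak_field = peak_field, fluence = fluence,
                 gdd = gdd, tod = tod, cep = cep),
            class = "pulse_spec")
}

#' Detection-noise specification for synthetic trace ensembles
#'
#' Emulates the statistics of repeated electro-optic-sampling scans:
#' additive field noise plus trace-to-trace pulse-energy fluctuations.
#'
#' @param additive_sigma std of additive field noise relative to the peak
#'   field (≥ 0)
#' @param power_jitter relative std of the per-trace field scale (≥ 0);
#'   the pulse energy fluctuates by about twice this
#' @param seed integer RNG seed
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(additive_sigma = 0, power_jitter = 0, seed = 1L) {
  stopifnot(additive_sigma >= 0, power_jitter >= 0)
  structure(list(additive_sigma = additive_sigma, power_jitter = power_jitter,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Real electric-field waveform on a time grid
#'
#' @param grid a [time_grid()]
#' @param field real field samples (V/m), same length as the grid
#' @param meta free-form provenance list (center, duration, chirp, seed, ...)
#' @return an object of class `waveform`
#' @export
waveform <- function(grid, field, meta = list()) {
  stopifnot(inherits(grid, "time_grid"), length(field) == grid$n,
            is.numeric(field), all(is.finite(field)))
  structure(list(grid = grid, field = as.numeric(field), meta = meta),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples, dt = %g fs, peak |E| = %.3g V/m\n",
              x$grid$n, x$grid$dt_fs, max(abs(x$field))))
  invisible(x)
}

# windowing contract: relative tail amplitude below `tol` of the peak
.check_windowed <- function(field, tol = 1e-6, what = "waveform") {
  pk <- max(abs(field))
  if (pk == 0) return(invisible(TRUE))
  edge <- max(abs(field[1]), abs(field[length(field)]))
  if (edge > tol * pk)
    .cet_stop(sprintf("%s does not vanish at the grid edges (%.2g of peak)",
                      what, edge / pk), "cet_window_error")
  invisible(TRUE)
}

#' Synthesize a few-cycle Gaussian excitation field
#'
#' Builds the real field \eqn{E(t) = E_0\, e^{-2\ln 2\, t^2/\tau^2}
#' \cos(\omega_0 t + \phi_{CEP})} whose intensity envelope has FWHM
#' \eqn{\tau}. If the spec requests a fluence, the amplitude is scaled so
#' the numerically integrated fluence matches it. A nonzero `gdd`/`tod` in
#' the spec is applied afterwards through [apply_chirp()].
#'
#' @param spec a [pulse_spec()]
#' @param grid a [time_grid()]; must be fine enough to sample the carrier
#'   (dt below a quarter period) and wide enough to contain the pulse
#' @return a [waveform()]
#' @export
make_gaussian_fce <- function(spec, grid) {
  stopifnot(inherits(spec, "pulse_spec"), inherits(grid, "time_grid"))
  w0 <- wavenumber_to_omega(spec$center_cm)
  # sampling: dt must stay below a quarter period at the carrier
  if (grid$dt_fs * 1e-15 > (2 * pi / w0) / 4)
    .cet_stop("grid too coarse for the requested carrier", "cet_sampling_error")
  t <- grid_times_s(grid)
  tau <- spec$fwhm_fs * 1e-15
  env <- exp(-2 * log(2) * t^2 / tau^2)
  E0 <- if (!is.null(spec$peak_field)) spec$peak_field else 1.0
  field <- E0 * env * cos(w0 * t + spec$cep)
  if (E0 != 0) .check_windowed(field, what = "generated pulse")
  w <- waveform(grid, field,
                meta = list(center_cm = spec$center_cm,
                            fwhm_fs = spec$fwhm_fs, cep = spec$cep,
                            gdd = spec$gdd, tod = spec$tod))
  if (!is.null(spec$fluence)) {
    f0 <- pulse_fluence(w)
    if (f0 <= 0 && spec$fluence > 0)
      .cet_stop("zero-amplitude pulse cannot carry fluence", "cet_spec_error")
    if (f0 > 0) w$field <- w$field * sqrt(spec$fluence / f0)
  }
  if (spec$gdd != 0 || spec$tod != 0)
    w <- apply_chirp(w, spec$gdd, spec$tod, spec$center_cm)
  w
}

#' Chirp a waveform by a Taylor-expanded spectral phase
#'
#' Multiplies the positive-frequency spectrum by
#' \eqn{\exp[-i(\tfrac12 \mathrm{gdd}\,(\omega-\omega_c)^2 +
#' \tfrac16 \mathrm{tod}\,(\omega-\omega_c)^3)]} (conjugate-symmetric on
#' the negative axis, so the field stays real). The energy spectral
#' density, and hence the pulse energy, is unchanged. A transform-limited
#' Gaussian of intensity FWHM \eqn{\tau} stretches to
#' \eqn{\tau\sqrt{1+(4\ln 2\, \mathrm{gdd}/\tau^2)^2}}.
#'
#' @param w a windowed [waveform()]
#' @param gdd group-delay dispersion (fs²)
#' @param tod third-order dispersion (fs³)
#' @param center_cm expansion wavenumber \eqn{\omega_c} (cm\eqn{^{-1}})
#' @return the chirped [waveform()]; errors if the stretched pulse no
#'   longer fits the grid
#' @export
apply_chirp <- function(w, gdd, tod, center_cm) {
  stopifnot(inherits(w, "waveform"))
  .check_windowed(w$field, tol = 1e-5, what = "input to apply_chirp")
  wc <- wavenumber_to_omega(center_cm)
  gdd_s <- gdd * 1e-30
  tod_s <- tod * 1e-45
  out <- .apply_filter(w$field, w$grid$dt_fs * 1e-15, function(om) {
    ph <- 0.5 * gdd_s * (abs(om) - wc)^2 + tod_s * (abs(om) - wc)^3 / 6
    exp(-1i * sign(om) * ph)
  })
  .check_windowed(out, tol = 1e-4, what = "chirped pulse")
  meta <- w$meta
  meta$gdd <- (meta$gdd %||% 0) + gdd
  meta$tod <- (meta$tod %||% 0) + tod
  waveform(w$grid, out, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symbolic impulsive (Dirac-delta) excitation
#'
#' A delta pulse of field-time area `area` (V·s/m) is never sampled on a
#' grid; it is consumed only by closed-form operations such as
#' [impulsive_budget()], where it drives every vibrational mode with the
#' same spectral amplitude `area` and kicks the coherence to
#' \eqn{|\rho(0^+)| = \mu\,A/\hbar}.
#'
#' @param area field-time area in V·s/m (nonzero)
#' @return an object of class `delta_pulse`
#' @export
make_delta_pulse <- function(area) {
  if (!is.numeric(area) || length(area) != 1 || area == 0)
    .cet_stop("delta pulse area must be a nonzero scalar", "cet_spec_error")
  structure(list(area = area), class = "delta_pulse")
}

#' Pulse fluence (energy per area)
#'
#' \eqn{F = c\,\varepsilon_0 \int E(t)^2\, dt} by trapezoidal quadrature on
#' the grid — the time integral of the instantaneous intensity (magnitude
#' of the Poynting vector), with no cycle averaging.
#'
#' @param w a [waveform()]
#' @return fluence in J/m²
#' @export
pulse_fluence <- function(w) {
  stopifnot(inherits(w, "waveform"))
  cet_constants$c * cet_constants$eps0 *
    pracma::trapz(grid_times_s(w$grid), w$field^2)
}

#' Synthetic measurement-like trace ensemble
#'
#' Emulates repeated field-resolved scans of the same waveform: each trace
#' is the input scaled by \eqn{1+\delta} with \eqn{\delta \sim N(0,
#' \mathrm{power\_jitter})} (a field-scale fluctuation, so the trace
#' *energy* jitters by about twice `power_jitter`), plus additive white
#' field noise of std `additive_sigma` × peak. Fully reproducible from the
#' seed, which is recorded in each trace's `meta`.
#'
#' @param w a [waveform()]
#' @param noise a [noise_spec()]
#' @param n_traces number of traces (≥ 1)
#' @return a list of [waveform()]s
#' @export
make_trace_ensemble <- function(w, noise, n_traces) {
  stopifnot(inherits(w, "waveform"), inherits(noise, "noise_spec"),
            n_traces >= 1)
  pk <- max(abs(w$field))
  set.seed(noise$seed)
  lapply(seq_len(n_traces), function(i) {
    scale <- 1 + noise$power_jitter * stats::rnorm(1)
    add <- if (noise$additive_sigma > 0)
      stats::rnorm(w$grid$n, sd = noise$additive_sigma * pk) else 0
    meta <- w$meta
    meta$ensemble_seed <- noise$seed
    meta$trace_index <- i
    waveform(w$grid, scale * w$field + add, meta)
  })
}

# Trace file I/O ---------------------------------------------------------

#' Read and write two-column ASCII field traces
#'
#' The on-disk format is `time_fs<TAB>field_V_per_m` with `#`-prefixed
#' header lines carrying `key = value` metadata; the reader also tolerates
#' comma or whitespace delimiters.
#'
#' @param w a [waveform()]
#' @param path file path
#' @return `read_trace` returns a [waveform()]; `write_trace` returns
#'   `path` invisibly
#' @export
write_trace <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(w$meta))
    if (is.atomic(w$meta[[k]]) && length(w$meta[[k]]) == 1)
      writeLines(sprintf("# %s = %s", k, format(w$meta[[k]], digits = 15)), con)
  writeLines("# time_fs\tfield_V_per_m", con)
  writeLines(sprintf("%.6f\t%.10e", grid_times_fs(w$grid), w$field), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in sub("^\\s*#\\s*", "", lines[hdr])) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "[,\t ]+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  t_fs <- m[, 1]
  dt <- diff(t_fs)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
    .cet_stop("trace file is not uniformly sampled", "cet_io_error")
  waveform(time_grid(t_fs[1], dt[1], nrow(m)), m[, 2], meta)
}
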