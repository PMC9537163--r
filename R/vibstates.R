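#' Fourier-grid Hamiltonian problem on a uniform 1D grid
#'
#' One-dimensional vibrational Schrödinger problem: a uniform coordinate
#' grid (atomic units, Bohr), potential samples, an optional dipole
#' function, and the reduced mass of the motion.
#'
#' @param x uniform coordinate grid (Bohr)
#' @param V potential samples (Hartree), bounded below
#' @param mu optional dipole-function samples (Debye) on the same grid
#' @param mass_amu reduced mass (unified atomic mass units)
#' @return an object of class `fgh_problem`
#' @export
fgh_problem <- function(x, V, mu = NULL, mass_amu = 1) {
  stopifnot(length(x) == length(V), length(x) >= 8, mass_amu > 0)
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-8 * abs(dx[1]))
    .cet_stop("FGH grid must be uniform", "cet_fgh_error")
  if (!is.null(mu)) stopifnot(length(mu) == length(x))
  structure(list(x = x, V = V, mu = mu, mass_amu = mass_amu),
            class = "fgh_problem")
}

#' Read a potential (and optional dipole) from CSV
#'
#' Columns `x_bohr, V_hartree` and optionally `mu_debye`; the curves are
#' interpolated onto a uniform grid with cubic splines.
#'
#' @param path CSV file
#' @param n number of uniform grid points
#' @param mass_amu reduced mass (amu)
#' @return an `fgh_problem`
#' @export
read_potential <- function(path, n = 256, mass_amu = 1) {
  df <- utils::read.csv(path)
  if (!all(c("x_bohr", "V_hartree") %in% names(df)))
    .cet_stop("potential file needs columns x_bohr, V_hartree",
              "cet_io_error")
  xs <- seq(min(df$x_bohr), max(df$x_bohr), length.out = n)
  V <- stats::spline(df$x_bohr, df$V_hartree, xout = xs)$y
  mu <- if ("mu_debye" %in% names(df))
    stats::spline(df$x_bohr, df$mu_debye, xout = xs)$y else NULL
  fgh_problem(xs, V, mu, mass_amu)
}

# amu -> electron masses; Hartree -> cm^-1
.amu_to_me <- 1822.888486
.hartree_to_cm <- 219474.6313632

#' Solve the 1D vibrational eigenproblem on the grid
#'
#' Dense diagonalization of the Fourier-grid Hamiltonian with the
#' uniform-grid sinc-DVR kinetic operator
#' \deqn{T_{ij} = \frac{\hbar^2 (-1)^{i-j}}{2 m\, \Delta x^2} \times
#' \begin{cases} \pi^2/3 & i = j \\ 2/(i-j)^2 & i \ne j, \end{cases}}
#' which converges exponentially with grid density for smooth potentials.
#' Energies are returned in cm\eqn{^{-1}} above the ground state; if a
#' dipole function is present, transition dipoles
#' \eqn{\langle\psi_0|\mu|\psi_k\rangle} are evaluated by grid quadrature.
#' Errors if the highest requested eigenfunction has not decayed at the
#' box edges.
#'
#' @param p an [fgh_problem()]
#' @param n_states number of eigenstates to return
#' @return an object of class `fgh_result` with `energies_cm` (length
#'   `n_states`, first element 0), `e0_hartree`, `wavefunctions` (columns
#'   normalized with \eqn{\sum \psi^2 \Delta x = 1}), and
#'   `transition_dipoles` (Debye, `NA` without a dipole function)
#' @export
fgh_solve <- function(p, n_states = 4) {
  stopifnot(inherits(p, "fgh_problem"), n_states >= 1)
  n <- length(p$x)
  dx <- p$x[2] - p$x[1]
  m <- p$mass_amu * .amu_to_me
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  Tmat <- (-1)^d * 2 / (d^2 + diag(n))  # diag placeholder, fixed next line
  diag(Tmat) <- pi^2 / 3
  Tmat <- Tmat / (2 * m * dx^2)
  Hmat <- Tmat + diag(p$V)
  eig <- eigen(Hmat, symmetric = TRUE)
  ord <- seq(n, n - n_states + 1)
  psi <- eig$vectors[, ord, drop = FALSE] / sqrt(dx)
  ev <- eig$values[ord]
  # edge-leakage check on the highest requested state
  hi <- abs(psi[, n_states])
  if (max(hi[c(1, n)]) > 1e-6 * max(hi))
    .cet_stop("highest requested eigenfunction leaks out of the box",
              "cet_fgh_error")
  tds <- if (!is.null(p$mu))
    vapply(seq_len(n_states), function(k)
      sum(psi[, 1] * p$mu * psi[, k]) * dx, 1.0)
  else rep(NA_real_, n_states)
  structure(list(energies_cm = (ev - ev[1]) * .hartree_to_cm,
                 e0_hartree = ev[1], wavefunctions = psi, x = p$x, dx = dx,
                 transition_dipoles = tds),
            class = "fgh_result")
}

#' @export
print.fgh_result <- function(x, ...) {
  cat("<fgh_result> transitions (cm-1):",
      paste(sprintf("%.2f", x$energies_cm[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' Transition dipole from the ground state
#'
#' Grid quadrature of \eqn{\langle\psi_0|\mu|\psi_k\rangle} for a solved
#' problem (`k = 0` is the ground state itself).
#'
#' @param res an `fgh_result` solved from a problem with a dipole function
#' @param k excited-state index (1-based above the ground state)
#' @return transition dipole in Debye
#' @export
transition_dipole <- function(res, k) {
  stopifnot(inherits(res, "fgh_result"), k >= 1,
            k + 1 <= ncol(res$wavefunctions))
  if (all(is.na(res$transition_dipoles)))
    .cet_stop("problem was solved without a dipole function", "cet_fgh_error")
  res$transition_dipoles[k + 1]
}

#' Autocorrelation of a classical dipole time series
#'
#' Unbiased estimator \eqn{C(k\Delta t) = \frac{1}{n-k}\sum_i x_i
#' x_{i+k}} up to half the series length, evaluated by FFT.
#'
#' @param series numeric dipole series (uniform sampling)
#' @param dt_fs sampling step (fs)
#' @return an object of class `acf_trace` with `lag_fs` and `acf`
#' @export
dipole_acf <- function(series, dt_fs) {
  n <- length(series)
  stopifnot(n >= 4, dt_fs > 0)
  npad <- .pad_length(n)
  Xw <- stats::fft(c(series, rep(0, npad - n)))
  raw <- Re(stats::fft(Mod(Xw)^2, inverse = TRUE)) / npad
  nl <- floor(n / 2)
  lags <- 0:(nl - 1)
  vals <- raw[lags + 1] / (n - lags)
  structure(list(lag_fs = lags * dt_fs, acf = vals), class = "acf_trace")
}

#' Line parameters from a dipole autocorrelation function
#'
#' Fourier-transforms the (Hann-windowed) ACF and fits a Lorentzian to
#' each of the `n_peaks` most prominent spectral peaks, returning center
#' wavenumbers and FWHMs — the dephasing rate follows as
#' \eqn{\Gamma = \pi c\,\mathrm{FWHM}}, closing the loop with the
#' Lorentz-oscillator linewidth convention. Peaks narrower than two
#' spectral bins are rejected as unresolved.
#'
#' @param acf an `acf_trace`
#' @param n_peaks number of Lorentzian components to extract
#' @return data frame with columns `nu_cm`, `fwhm_cm`, `gamma_inv_fs`
#' @export
gamma_from_acf <- function(acf, n_peaks = 1) {
  stopifnot(inherits(acf, "acf_trace"), n_peaks >= 1)
  n <- length(acf$acf)
  dt <- (acf$lag_fs[2] - acf$lag_fs[1]) * 1e-15
  hann <- 0.5 * (1 + cos(pi * (0:(n - 1)) / (n - 1)))  # half window: lag >= 0
  npad <- .pad_length(n)
  spec <- Re(stats::fft(c(acf$acf * hann, rep(0, npad - n))))
  om <- .fft_omega(npad, dt)
  pos <- om > 0
  nu <- omega_to_wavenumber(om[pos])
  y <- spec[pos]
  o <- order(nu)
  nu <- nu[o]
  y <- y[o]
  dnu <- nu[2] - nu[1]
  loc <- which(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)]) + 1L
  loc <- loc[order(-y[loc])]
  if (length(loc) < n_peaks)
    .cet_stop("fewer spectral peaks than requested", "cet_fit_error")
  loc <- sort(loc[seq_len(n_peaks)])
  fits <- lapply(loc, function(i) {
    win <- abs(nu - nu[i]) < max(60, 40 * dnu)
    lor <- function(p) p[3] * (p[2] / 2)^2 / ((nu[win] - p[1])^2 + (p[2] / 2)^2)
    p0 <- c(nu[i], max(10 * dnu, 5), y[i])
    ft <- minpack.lm::nls.lm(p0, fn = function(p) lor(p) - y[win],
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    c(ft$par[1], abs(ft$par[2]))
  })
  out <- do.call(rbind, fits)
  if (any(out[, 2] < 2 * dnu))
    .cet_stop("spectral peak unresolved (FWHM below two bins)",
              "cet_resolution_error")
  data.frame(nu_cm = out[, 1], fwhm_cm = out[, 2],
             gamma_inv_fs = dephasing_time_fs(out[, 2]))
}
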