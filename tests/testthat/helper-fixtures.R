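# Shared, lazily computed fixtures (memoized across test files).
.fx <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx)) {
    val <- switch(
      name,
      grid = time_grid(),
      fce = make_gaussian_fce(pulse_spec(1260, 62.5, peak_field = 7.5e6),
                              fx("grid")),
      cpe = apply_chirp(fx("fce"), -13500, 0, 1260),
      expt = sample_preset("table1_experiment"),
      expl = sample_preset("table1_explicit_solvation"),
      fce_trans = propagate(fx("fce"), fx("expt")),
      fce_cet = cet(fx("fce"), fx("fce_trans")),
      cpe_trans = propagate(fx("cpe"), fx("expt")),
      cpe_cet = cet(fx("cpe"), fx("cpe_trans")),
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fx)
  }
  get(name, envir = .fx)
}

# small grid for noise/ensemble tests (keeps memory and runtime low)
small_grid <- function(n = 2001) time_grid(-200, 0.5, n)

small_pulse <- function(grid = small_grid(), center = 1200, fwhm = 40,
                        peak = 1e6)
  make_gaussian_fce(pulse_spec(center, fwhm, peak_field = peak), grid)

# atomic-unit constants and a harmonic oracle problem for the eigensolver
me_per_amu <- 1822.888486
hartree_cm <- 219474.6313632

harmonic_problem <- function(nu_cm = 1148, mass_amu = 10, half_width = 1.5,
                             n = 301, mu = NULL) {
  w0 <- nu_cm / hartree_cm
  m <- mass_amu * me_per_amu
  x <- seq(-half_width, half_width, length.out = n)
  fgh_problem(x, 0.5 * m * w0^2 * x^2, mu = mu, mass_amu = mass_amu)
}

# intensity-envelope FWHM measured from the analytic-signal envelope
measured_fwhm_fs <- function(w) {
  env2 <- Mod(cetscope:::analytic_signal(w$field))^2
  t_fs <- grid_times_fs(w$grid)
  half <- max(env2) / 2
  above <- which(env2 >= half)
  lo <- min(above); hi <- max(above)
  li <- stats::approx(env2[c(lo - 1, lo)], t_fs[c(lo - 1, lo)], half)$y
  ri <- stats::approx(env2[c(hi + 1, hi)], t_fs[c(hi + 1, hi)], half)$y
  ri - li
}
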