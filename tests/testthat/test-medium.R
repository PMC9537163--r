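nu_axis <- function(from = 900, to = 1600, by = 0.25)
  wavenumber_to_omega(seq(from, to, by = by))

test_that("susceptibility has the Lorentz-oscillator structure", {
  s0 <- sample_preset("table1_experiment", beta_mg_ml = 0)
  expect_true(all(susceptibility(s0, nu_axis())$chi == 0))
  s1 <- sample_spec(vib_mode(1148, 0.33), beta_mg_ml = 10)
  om <- nu_axis(1000, 1300, 0.02)
  chi <- susceptibility(s1, om)$chi
  wk <- wavenumber_to_omega(1148)
  # |Im chi| peaks at the resonance; Re chi crosses zero there
  expect_lt(abs(om[which.max(abs(Im(chi)))] - wk), wavenumber_to_omega(0.05))
  zc <- om[which(diff(sign(Re(chi))) != 0)][1]
  expect_lt(abs(zc - wk), wavenumber_to_omega(0.05))
  # absorbing sign under the package convention, dilute magnitude
  expect_lt(Im(chi)[which.max(abs(Im(chi)))], 0)
  expect_lt(max(Mod(chi)), 0.1)
  # Hermitian symmetry on a signed axis
  expect_equal(susceptibility(s1, -om)$chi, Conj(chi))
})

test_that("Kramers-Kronig / causality of the transfer function", {
  s <- fx("expt")
  dt <- 0.5e-15
  npad <- 32768
  om <- cetscope:::.fft_omega(npad, dt)
  # band-limited probe spanning the mid-IR coverage (the raw H has slowly
  # decaying 1/w dispersive phase up to the Nyquist edge, which a physical
  # band-limited field never samples)
  W <- exp(-(abs(omega_to_wavenumber(om)) - 1250)^2 / (2 * 300^2))
  Hw <- (transfer_function(susceptibility(s, om), s$length_um) - 1) * W
  ir <- Re(stats::fft(Hw, inverse = TRUE)) / npad
  # the response to the probe lives at t >= 0 apart from the probe's own
  # ~20 fs width: nothing beyond a 100 fs guard band before zero
  t_ir <- c(0:(npad / 2 - 1), -(npad / 2):-1) * 0.5  # fs, fft layout
  neg <- ir[t_ir < -100]
  expect_lt(max(abs(neg)), 1e-6 * max(abs(ir)))
  # reconstructing from the causal projection reproduces the spectrum (KK)
  ir_causal <- ir
  ir_causal[t_ir < -100] <- 0
  H2 <- stats::fft(ir_causal)
  core <- abs(om - wavenumber_to_omega(1250)) < wavenumber_to_omega(300)
  expect_lt(max(Mod(H2[core] - Hw[core])), 0.01 * max(abs(Re(Hw))))
})

test_that("transfer function is passive and thin-sample limit is quadratic", {
  s <- fx("expt")
  for (m in s$modes) {
    wk <- wavenumber_to_omega(m$nu_cm)
    expect_lt(Mod(transfer_function(susceptibility(s, wk), s$length_um)), 1)
  }
  expect_equal(transfer_function(susceptibility(s, nu_axis()), 0),
               rep(1 + 0i, length(nu_axis())))
  # thin-vs-exact deviation is O(chi w L / c)^2: quadratic in concentration
  dev_at <- function(beta) {
    sb <- sample_preset("table1_experiment", beta_mg_ml = beta)
    chi <- susceptibility(sb, nu_axis())
    max(Mod(transfer_function(chi, 30) - transfer_function(chi, 30, thin = TRUE)))
  }
  d1 <- dev_at(1); d10 <- dev_at(10)
  expect_lt(d1, 1e-3)
  expect_equal(d10 / d1, 100, tolerance = 0.25)
})

test_that("propagation is linear, real, passive, and exact at beta = 0", {
  w <- fx("fce")
  s0 <- sample_preset("table1_experiment", beta_mg_ml = 0)
  expect_lt(max(abs(propagate(w, s0)$field - w$field)) / max(abs(w$field)),
            1e-10)
  out <- fx("fce_trans")
  expect_true(is.numeric(out$field))
  a <- 2.7
  wa <- waveform(w$grid, a * w$field, w$meta)
  expect_lt(max(abs(propagate(wa, fx("expt"))$field - a * out$field)) /
              max(abs(a * out$field)), 1e-10)
  # passive: output ESD never exceeds input ESD
  ein <- esd(w); eout <- esd(out)
  expect_true(all(eout$esd <= ein$esd * (1 + 1e-9) + 1e-10 * max(ein$esd)))
  # a grid too short for the free-induction decay is rejected
  wshort <- make_gaussian_fce(pulse_spec(1260, 62.5, peak_field = 1e6),
                              time_grid(-300, 0.5, 2401))
  expect_error(propagate(wshort, fx("expt")), class = "cet_window_error")
})

test_that("absorbance reproduces the two SO2 stretching bands", {
  ab <- absorbance(fx("fce"), fx("fce_trans"), seq(950, 1500, by = 0.5))
  # identical fields give zero
  ab0 <- absorbance(fx("fce"), fx("fce"), seq(950, 1500, by = 2))
  expect_lt(max(abs(ab0$absorbance), na.rm = TRUE), 1e-9)
  # the two fitted-mode maxima sit at 1135 and 1280 cm-1
  pk <- ab$nu_cm[which.max(ab$absorbance)]
  expect_equal(pk, 1280, tolerance = 2 / 1280)
  lo <- ab[ab$nu_cm < 1200, ]
  expect_equal(lo$nu_cm[which.max(lo$absorbance)], 1135, tolerance = 2 / 1135)
  # out-of-band bins are masked, with a warning when nothing remains
  expect_warning(absorbance(fx("fce"), fx("fce_trans"), seq(4000, 4100, 10)),
                 "floor")
})

test_that("weak-line peak absorbance matches the closed form", {
  s <- sample_spec(vib_mode(1148, 0.33), beta_mg_ml = 0.5)
  w <- fx("fce")
  ab <- absorbance(w, propagate(w, s), seq(1100, 1200, by = 0.1))
  cc <- cet_constants
  N <- 0.5 * cc$NA_ / (94.13e-3)
  alpha_pk <- N * debye_to_Cm(0.33)^2 * wavenumber_to_omega(1148) /
    (3 * cc$hbar * cc$eps0 * fwhm_to_gamma(19.4) * cc$c)
  A_pk <- alpha_pk * 30e-6 / (2 * log(10))  # amplitude-log convention
  expect_equal(max(ab$absorbance, na.rm = TRUE), A_pk, tolerance = 0.03)
})

test_that("mode tables load from CSV and presets carry the printed values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nu_cm1,mu_debye,fwhm_cm1", "1135,0.30,19.4", "1280,0.38,19.4"),
             path)
  s <- read_mode_table(path)
  e <- fx("expt")
  expect_equal(vapply(s$modes, `[[`, 1.0, "nu_cm"),
               vapply(e$modes, `[[`, 1.0, "nu_cm"))
  expect_equal(vapply(s$modes, `[[`, 1.0, "mu_debye"), c(0.30, 0.38))
  ex <- sample_preset("table1_explicit_solvation")
  expect_equal(vapply(ex$modes, `[[`, 1.0, "nu_cm"), c(1148, 1301))
  expect_equal(vapply(ex$modes, `[[`, 1.0, "mu_debye"), c(0.33, 0.41))
  expect_error(sample_preset("nope"), class = "cet_spec_error")
})
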