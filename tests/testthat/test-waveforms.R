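test_that("linewidth and unit conversions are mutually consistent", {
  expect_equal(dephasing_time_fs(19.4), 547.3, tolerance = 1e-3)
  expect_equal(gamma_to_fwhm(fwhm_to_gamma(19.4)), 19.4)
  expect_equal(omega_to_wavenumber(wavenumber_to_omega(1148)), 1148)
  # 1148 cm-1 corresponds to a 29 fs optical period
  expect_equal(2 * pi / wavenumber_to_omega(1148) * 1e15, 29.05,
               tolerance = 1e-3)
})

test_that("Gaussian pulse matches its specification", {
  w <- fx("fce")
  expect_equal(measured_fwhm_fs(w), 62.5, tolerance = 0.01)
  sp <- esd(w)
  expect_equal(sp$nu_cm[which.max(sp$esd)], 1260, tolerance = 2e-3)
  # >99% of the pulse energy inside the stated 850-1670 cm-1 coverage
  inband <- sp$nu_cm >= 850 & sp$nu_cm <= 1670
  expect_gt(sum(sp$esd[inband]) / sum(sp$esd), 0.99)
  # zero amplitude in, zero field out
  w0 <- make_gaussian_fce(pulse_spec(1260, 62.5, peak_field = 0), fx("grid"))
  expect_true(all(w0$field == 0))
  # a grid coarser than a quarter period is rejected
  expect_error(make_gaussian_fce(pulse_spec(1260, 62.5, peak_field = 1),
                                 time_grid(-500, 8, 201)),
               class = "cet_sampling_error")
})

test_that("fluence handling: closed form, quadratic scaling, requested value", {
  E0 <- 2e6; tau <- 62.5
  w <- make_gaussian_fce(pulse_spec(1260, tau, peak_field = E0), fx("grid"))
  closed <- 0.5 * cet_constants$c * cet_constants$eps0 * E0^2 *
    tau * 1e-15 * sqrt(pi / log(16))
  expect_equal(pulse_fluence(w), closed, tolerance = 0.01)
  w2 <- waveform(w$grid, 2 * w$field)
  expect_equal(pulse_fluence(w2) / pulse_fluence(w), 4, tolerance = 1e-12)
  wf <- make_gaussian_fce(pulse_spec(1260, tau, fluence = 3e-4), fx("grid"))
  expect_equal(pulse_fluence(wf), 3e-4, tolerance = 1e-3)
  expect_error(pulse_spec(1260, 62.5), class = "cet_spec_error")
  expect_error(pulse_spec(1260, 62.5, peak_field = 1, fluence = 1),
               class = "cet_spec_error")
})

test_that("chirp is unitary and follows the Gaussian stretch law", {
  w <- fx("fce")
  # zero chirp is the identity
  wi <- apply_chirp(w, 0, 0, 1260)
  expect_lt(max(abs(wi$field - w$field)) / max(abs(w$field)), 1e-10)
  # energy and spectrum are conserved
  wc <- fx("cpe")
  expect_equal(pulse_fluence(wc) / pulse_fluence(w), 1, tolerance = 1e-6)
  e1 <- esd(w); e2 <- esd(wc)
  expect_lt(max(abs(e2$esd - e1$esd)) / max(e1$esd), 1e-6)
  # duration: tau' = tau sqrt(1 + (4 ln2 gdd / tau^2)^2)
  gdd <- -13500; tau <- 62.5
  stretch <- tau * sqrt(1 + (4 * log(2) * gdd / tau^2)^2)
  expect_equal(measured_fwhm_fs(wc), stretch, tolerance = 0.02)
  # a chirp that no longer fits the window is rejected
  wshort <- make_gaussian_fce(pulse_spec(1200, 40, peak_field = 1e6),
                              time_grid(-400, 0.5, 1601))
  expect_error(apply_chirp(wshort, 2e5, 0, 1200), class = "cet_window_error")
})

test_that("delta pulse is symbolic and rejects zero area", {
  d <- make_delta_pulse(3e-9)
  expect_s3_class(d, "delta_pulse")
  expect_error(make_delta_pulse(0), class = "cet_spec_error")
})

test_that("trace ensembles reproduce the requested statistics", {
  w <- small_pulse()
  # no noise: identical copies
  ens0 <- make_trace_ensemble(w, noise_spec(0, 0, seed = 7), 3)
  expect_identical(ens0[[1]]$field, w$field)
  expect_identical(ens0[[3]]$field, w$field)
  # bit-identical reproduction from the same seed
  e1 <- make_trace_ensemble(w, noise_spec(0.01, 0.01, seed = 42), 5)
  e2 <- make_trace_ensemble(w, noise_spec(0.01, 0.01, seed = 42), 5)
  expect_identical(lapply(e1, `[[`, "field"), lapply(e2, `[[`, "field"))
  # 1% field-scale jitter -> ~2% std of per-trace energies
  ens <- make_trace_ensemble(w, noise_spec(0, 0.01, seed = 1), 1000)
  en <- vapply(ens, pulse_fluence, 1.0)
  rel_sd <- stats::sd(en) / mean(en)
  # sampling error of the std at n = 1000 is ~ 2%/sqrt(2n) ~ 0.045%
  expect_equal(rel_sd, 0.02, tolerance = 0.1)
})

test_that("ensemble mean converges to the clean waveform", {
  g <- time_grid(-100, 1, 201)
  w <- small_pulse(g, fwhm = 20)
  n <- 10000
  ens <- make_trace_ensemble(w, noise_spec(0.05, 0, seed = 3), n)
  m <- rowMeans(vapply(ens, `[[`, numeric(g$n), "field"))
  se <- 0.05 * max(abs(w$field)) / sqrt(n)
  # pointwise errors are ~N(0, se); the largest of 201 draws is ~3.3 se
  expect_lt(max(abs(m - w$field)), 5 * se)
  expect_equal(sqrt(mean((m - w$field)^2)), se, tolerance = 0.3)
})

test_that("trace files round-trip through the ASCII format", {
  w <- small_pulse()
  w$meta$center_cm <- 1200
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(w, path)
  r <- read_trace(path)
  expect_equal(r$field, w$field, tolerance = 1e-9)
  expect_equal(r$meta$center_cm, 1200)
  expect_equal(grid_times_fs(r$grid), grid_times_fs(w$grid), tolerance = 1e-9)
  # comma-delimited input is tolerated
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# center_cm = 1200", paste(grid_times_fs(w$grid), w$field,
                                           sep = ",")), path2)
  r2 <- read_trace(path2)
  expect_equal(r2$field, w$field, tolerance = 1e-9)
})
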